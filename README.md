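# endofuse

Membrane-biophysics modelling and quantification of the two modes of
endosomal fusion.  Late endosomes fuse either *explosively* — the fusion
pore snaps open and two vesicles round up into one within tens of
seconds — or by *bridge fusion*, where the pore stays narrow and one
vesicle slowly drains into its partner (typically a lysosome) until it
disappears.  `endofuse` is for quantitative cell biologists and membrane
biophysicists who want to (a) compute which mode a vesicle pair of a given
size, osmotic load and fluctuation level should select, and (b) quantify
fusion kinetics and FRAP turnover from vesicle track tables.

## The model

A two-lobed closed membrane with a constricted neck is described by the
neck width `w` (waist radius / radius of the area-equivalent sphere) and
the smaller lobe's area fraction `a`.  Its free energy is

    F = b − Δp·V,      b = (κ/2) ∮ (2H)² dS

with bending modulus κ = 10 kBT, osmotic pressure difference Δp ≈ 2.5–25
Pa and a minimum bending radius R0 = 100 nm regularising the neck.  For
small vesicles F ≈ b (scale-free): descent on the (w, a) landscape opens
the neck → explosive fusion.  For large vesicles F ≈ B_neck − Δp·V: the
osmotic term drives absorption of the smaller lobe at a narrow neck →
bridge fusion.  Constrained minimum-energy shapes are built analytically
(spherical caps + toroidal/catenoid collar), landscapes are evaluated on a
(w, a) grid, and deformation orbits — deterministic gradient descent or
overdamped Langevin with fluctuation energy `E_fluct` (kBT) — are
classified by first crossings (`w ≥ 0.2` → explosive, `a ≤ 0.02` →
bridge).  The crossover size solving Δp·V(A*) = b with b = 2×10⁻¹⁸ J is
0.22–1.0 μm² over the working pressure range.

A seeded generator produces vesicle populations, track tables with merge
and shrink signatures, fusion-event samples with size–duration coupling,
and FRAP curves; the quantification module detects events, computes
fusion-time/frequency statistics, Pearson size–time correlations,
Mann-Whitney size comparisons and FRAP half-times.  See the methods
vignette (`vignettes/fusion-mode-selection.Rmd`) for assumptions and
numerical choices.

## Worked example

```r
library(endofuse)

## crossover size at the upper working pressure
crossover_area(b = 2e-18, delta_p_Pa = 25)
#> Fusion-mode crossover size
#>   b = 2e-18 J, delta_p = 25 Pa
#>   A* = 0.2245 um^2 (V* = 0.08 um^3)

## large-vesicle landscape and the deterministic post-pore orbit
L <- compute_landscape(mode = "large", A_p = 10,
                       phys = physical_params(delta_p_Pa = 10))
gradient_orbit(L)
#> Fusion orbit
#>   init (w, a) = (0, 0.3), E_fluct = 0 kBT, steps = 39
#>   final (w, a) = (0.0000, 0.0200); classification: bridge

## thermal vs cytoskeletal fluctuation levels
phase_diagram(A_p_um2 = 10, delta_p_Pa = 10, E_fluct_kBT = c(1, 1e4),
              n_runs = 200, seed = 1)[, c("E_fluct_kBT", "P_explosive")]

## synthetic tracks through the measurement pipeline
cfg <- fusion_generator_config(seed = 1)
tracks <- simulate_tracks(cfg, n_vesicles = 30, scenario = "mixed", seed = 7)
events <- detect_fusion_events(tracks)
fusion_statistics(events[events$type == "homotypic", ],
                  n_vesicles = 30, duration_s = 400)
#> Fusion statistics
#>   n = 12, mean = 31.50 s (SEM 0.532 s)
#>   frequency = 0.0600 fusions / min / vesicle

## FRAP half-recovery
fit_frap(simulate_frap(cfg, "cell_surface", seed = 7))
#> FRAP half-recovery
#>   t1/2 (model-free crossing) = 28.46 s
#>   t1/2 (mono-exponential fit) = 29.52 s
#>   plateau = 0.918, post-bleach floor = 0.242 (pre-bleach = 1)
```

The orbit classification says a 10 μm² vesicle pair under 10 Pa with
thermal noise should drain through a narrow neck (bridge fusion); the
fusion statistics and FRAP estimates recover the generator's calibrated
kinetics (homotypic mean 31.9 s, cell-surface t½ 29.0 s) within sampling
error.

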