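# epibuckle

Mechanics and morphometrics of junctional buckling in growing,
non-dividing epithelial cell nests.

## The problem

Most epithelia keep straight, polygonal cell outlines because their
adherens-junction network is under tension. Histoblasts — the larval
precursors of the adult *Drosophila* abdominal epidermis — violate this rule:
over the last larval stage they grow without dividing while the apical
surface available to them shrinks, and their junctions fold into deep,
puzzle-piece lobules. Mechanically this is a buckling problem: the junctional
belt keeps adding material (rest length grows as `l_rest <- (1 + dt g_b)
l_rest`) while the domain contracts, so junctions are compressed past their
critical load. Two signatures separate it from a textbook Euler beam, and
both are reproduced here: buckling occurs at **high mode** (several
undulations per junction), because the junction is coupled to an elastic
(Winkler) foundation — the surrounding apical cortex — which penalises
long-wavelength deflection; and severed junctions **hardly recoil**, because
the foundation re-anchors plastically around the buckled shape and
dissipates the stored stress.

`epibuckle` is for quantitative biologists and biophysicists who want to
simulate this regime and compute the statistics used to characterise it.

## The model in brief

Cell boundaries are spring chains: vertices with positions `P`, edges with
rest lengths `l_rest` and axial force `F = k_b (l/l_rest - 1)`, angular
springs at chain vertices with torque `k_bend (theta - theta_rest)`
(`theta_rest = 2*pi/n`), an elastic foundation `F = k_f (P_f - P)` whose
anchors creep toward the vertices (`P_f <- P_f + (P - P_f) dt_f`, the
plasticity), and transient compression-only penalty springs that prevent
boundary self-contact (rest length on the tangent circle of diameter
`Th_sub`). Each iteration: place connections, grow rest lengths and shrink
the template along x, relax to mechanical equilibrium (backward-Euler
proximal steps, energy provably non-increasing), subdivide segments longer
than `Th_sub`, move the anchors. All defaults are the published parameter
set; see `?sim_params` and the methods vignette
(`vignettes/junctional-buckling-methods.Rmd`).

The classic beam results act as oracles for the physics: the critical load
of a pinned beam scales as `P_c = pi^2 B / L^2` (`euler_buckling_scan()`
recovers exponent -2), and a beam on a Winkler foundation buckles at
`lambda = 2 pi (B/k)^(1/4)` (`foundation_mode_scan()` recovers exponent
-1/4).

## Worked example

```r
library(epibuckle)

params <- sim_params()                       # published defaults
nest <- make_cell_grid(width = 24, height = 24, n_cells = 6, seed = 1)
nest <- subdivide_long_edges(nest, params$th_sub)
nest <- init_rest_state(nest, params)        # zero-energy rest state
nest
#> <tissue_mesh> 221 vertices (128 fixed), 226 edges, 6 faces

res <- run_simulation(nest, params, steps = 120, snapshot_every = 0)
res$log[c(1, 60, 120), c("step", "mean_circularity", "template_width", "n_connections")]
#>     step mean_circularity template_width n_connections
#> 1      1            0.754         23.928             0
#> 60    60            0.519         20.041             3
#> 120  120            0.297         16.735            50
```

Mean circularity (`4*pi*A/P^2`, 1 for a circle) falls from ~0.75 to ~0.30 as
the template contracts and the growing junctions buckle — the morphological
transition. `template_width` is the x-extent of the shrinking frame (um);
`n_connections` counts the self-contact penalty springs, which appear once
lobules start to crowd. Per-cell statistics of the final state:

```r
head(mesh_stats(res$mesh), 3)
#>   cell_id    area perimeter circularity simple
#> 1       1 105.891    60.779       0.360   TRUE
#> 2       2  49.994    45.384       0.305   TRUE
#> 3       3  95.186    58.609       0.348   TRUE
```

Other entry points: `ablate()` (in-silico laser dissection),
`euler_buckling_scan()` / `foundation_mode_scan()` (beam physics),
`junction_straightness()`, `vertex_fluctuation_rms()`,
`morphospace_summary()`, `junctional_enrichment()`, `thickness_map()`
(image quantification), and the `make_*` synthetic-data generators, each of
which returns its ground truth.

## Command line

A single entry point with subcommands lives in `exec/epibuckle`:

```sh
exec/epibuckle init --width 55 --height 55 --n-cells 16 --seed 1 --out mesh.txt
exec/epibuckle simulate --mesh mesh.txt --steps 150 --out run/
exec/epibuckle stats --mesh run/snapshot_150.txt --out stats.csv
exec/epibuckle synth zstack --seed 1 --thickness 6 --out fixtures/demo
```

Every run writes a JSON manifest (canonical config hash, seed, version)
beside its outputs; identical config + seed gives identical hashes and
bit-identical outputs. All file formats are plain text (sectioned mesh
files, JSON configs, CSV tables/images, a one-header text z-stack format).

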