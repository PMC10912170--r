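# periglia

Quantification of microglia–neuron soma contact and the displacement of
perisomatic GABAergic synapses, as an R package with a fully synthetic,
ground-truthed validation pipeline.

## The scientific problem

Satellite microglia sit directly on neuronal cell bodies. Where a
microglial soma covers part of a neuronal soma, the VGAT-positive
inhibitory boutons that normally stud that membrane are not destroyed but
*displaced*: per-pair bouton totals are conserved while the count on the
neuronal surface falls and the count on the microglial surface rises, and
truly engulfed boutons (inside the microglia) remain a small, separate
population. Downstream, this remodelling of perisomatic inhibition is
read out as changed calcium-transient frequency in the contacted neurons
and changed gamma-band (30–100 Hz) power in the local field potential.

Quantifying this requires a chain of measurements that are usually done
in commercial 3D software and are hard to audit:

* **Extensive association.** A microglia–neuron pair is "extensively
  associated" when the microglia covers more than 25 % of the neuronal
  circumference in a single 2D plane, or — via the 2D→3D calibration
  regression `Y = 0.545 X − 0.355` (coverages in percent) — at least
  **13.27 %** of the soma surface in a 3D reconstruction:
  `0.545 × 25 − 0.355 = 13.27`.
* **Contact geometry.** Per nearest microglia–neuron pair: contact area
  (µm²) and surface coverage, from closed triangle meshes reconstructed
  from instance labels; validated against a brute-force voxel-adjacency
  oracle.
* **Synapse counting.** VGAT-like puncta (0.5 µm xy / 1 µm z) are
  detected, then classified by signed distance to the paired surfaces:
  within 0.5 µm outside the neuron → on-neuron; within 0.5 µm outside the
  microglia → on-microglia; negative distance to the microglia →
  engulfed.
* **Motility** (co-culture time lapse): movement classes (+1 towards, 0
  immobile, −1 away), the cohort association index, and approach speed
  binned by distance in folds of the soma radius.
* **Signals:** ΔF/F calcium-transient frequency and Welch PSD gamma-band
  power normalised by a baseline recording.
* **Statistics:** cells are nested in animals, so group comparisons use
  an animal-clustered bootstrap-t; the animal is the unit everywhere.

Because raw micrographs for such studies are rarely deposited, the
package ships a synthetic-tissue generator (`simulate_volume()`,
`simulate_coculture_tracks()`, `simulate_calcium()`, `simulate_lfp()`)
that plants all of these effects with known ground truth, so every stage
of the pipeline is validated by recovery experiments.

## Worked example

Simulate a multi-animal cohort of microglia–neuron pairs with a planted
40 % displacement under associated microglia, run the full geometry
pipeline, and compare groups with the clustered bootstrap (this is
`analysis/03_synapse_displacement.R`):

```r
library(periglia)

cohort <- simulate_pair_cohort(n_animals = 5, pairs_per_animal = 60,
                               seed = 11, voxel_size = c(0.6, 0.6, 0.6),
                               p_assoc = 0.3, displace_frac = 0.4,
                               coverage_nonassoc = 0.02)
mean(cohort$extensive_3d)          # 0.263 -- recovered association rate
grp <- ifelse(cohort$extensive_3d, "associated", "non_associated")
long <- function(m) data.frame(animal_id = cohort$animal, group = grp,
                               value = cohort[[m]])
cluster_bootstrap_diff(long("n_on_neuron"), "associated", "non_associated",
                       n_boot = 2000, seed = 11)
```

Printed output of the driver script:

```
cohort: 300 pairs, 26.3% extensively associated
median puncta on the neuronal soma by group:
           group median
1     associated     27
2 non_associated     46
n_on_neuron     diff  -17.77  CI [ -20.05,  -15.22]  p = 0.0005
n_on_microglia  diff  +16.86  CI [  15.20,   18.83]  p = 0.0005
n_pair_total    diff   -0.92  CI [  -4.30,    2.13]  p = 0.4903
n_engulfed      diff   -0.00  CI [  -0.52,    0.49]  p = 0.9970
```

Reading: associated pairs carry ~18 fewer boutons on the neuronal soma
and ~17 more on the microglial soma; pair totals and engulfed counts do
not differ — displacement, not loss, and not phagocytosis. The whole
analysis workflow lives in `analysis/01…06`, each a short driver that
writes its tables under `results/`.

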