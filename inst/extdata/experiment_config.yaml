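# Annotated experiment configuration for aieclust::read_experiment_config().
# Every key is optional; omitted keys take the package defaults shown here.
# Unknown keys raise an error naming them.

cell_model: clustered        # "clustered" (SKBR3-like) or "dispersed" (MCF7-like)
doses: [0, 0.01, 0.1, 1, 10, 100]   # ug/mL, must include 0 (untreated control)
times: [2, 8, 24]            # exposure times, hours
replicates: 3                # wells per condition
n_cells: 6                   # cells imaged (and pooled) per well

mean_radius: 5000            # footprint mean radius, nm
irregularity: 0.25           # radial perturbation amplitude, [0, 1)

cluster:                     # Thomas process of the clustered membrane
  kappa: 0.4                 # cluster centres per um^2
  mu: 25                     # mean receptors per cluster
  sigma: 30                  # offspring scatter, nm
  hardcore: 2                # minimum receptor separation, nm
background_intensity: 15     # dispersed pool under the clusters, per um^2
csr_intensity: 15            # dispersed model intensity, per um^2

disruption:                  # dose/time-dependent cluster relocation
  p_max: 0.8                 # saturating relocation probability
  ec50: 1                    # ug/mL
  hill: 1
  tau: 8                     # hours

aie:                         # proximity-gated emission rule
  d_min: 2.13                # nm (closed window)
  d_max: 6.62                # nm
  unit_brightness: 150       # photons per emissive fluorophore
conventional_brightness: 150 # photons per conventional fluorophore
labeling_efficiency: 0.9
dye_mode: single             # or "poisson_dar" with mean `dar` dyes/antibody
dar: 1.35

optics:
  pixel_size: 325            # nm per pixel (6.5 um camera pixel / 20x)
  psf_sigma: 170             # nm
  background: 10             # photons per pixel
  read_noise_sd: 3           # photons
  image_shape: [64, 64]      # rows, cols

segmentation:
  smooth_sigma: 3            # px
  gradient_threshold_method: otsu
  closing_radius: 3          # px
  min_object_area: 50        # px
  edge_erosion_radius: 4     # px; omit for the automatic choice

master_seed: 1
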