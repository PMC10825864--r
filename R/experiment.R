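#' Configuration of a simulated plate experiment
#'
#' Bundles every parameter of the end-to-end forward simulation: footprint
#' geometry, receptor-field model, disruption model, both emission rules,
#' optics, segmentation, and the dose/time/replicate grid. Defaults encode
#' the study conditions: a serial-dilution dose grid 0-100 ug/mL,
#' exposures of 2, 8 and 24 h, triplicate wells, and a clustered
#' ("SKBR3-like") membrane; `cell_model = "dispersed"` gives the
#' low-expression, unclustered ("MCF7-like") counterpart at
#' `csr_intensity` receptors per um^2.
#'
#' A clustered membrane is simulated as the superposition of a Thomas
#' cluster process and a dispersed (CSR) receptor pool of
#' `background_intensity` receptors per um^2: overexpressing cells carry a
#' high uniform membrane expression on top of their clusters, which is
#' also what makes the cell a contiguous object in the conventional-dye
#' channel that the segmentation stage relies on.
#'
#' @param cell_model `"clustered"` or `"dispersed"`.
#' @param doses dose grid, ug/mL; must contain 0 (the untreated control).
#' @param times exposure times, h.
#' @param replicates wells per condition.
#' @param n_cells cells imaged per well; the well statistic pools them.
#' @param mean_radius,irregularity footprint geometry
#'   (see [sample_cell_footprint()]).
#' @param cluster a [cluster_params()] (clustered model).
#' @param background_intensity dispersed receptor pool underlying the
#'   clusters, receptors per um^2 (clustered model only).
#' @param csr_intensity receptors per um^2 for the dispersed model.
#' @param disruption a [disruption_params()].
#' @param aie an [aie_params()].
#' @param conventional_brightness photons per conventional fluorophore.
#' @param labeling_efficiency per-receptor labeling probability.
#' @param dye_mode,dar see [aie_emission()].
#' @param optics an [optics_params()].
#' @param segmentation a [segmentation_params()].
#' @param master_seed default master seed for [run_experiment()].
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(cell_model = c("clustered", "dispersed"),
                              doses = c(0, 0.01, 0.1, 1, 10, 100),
                              times = c(2, 8, 24),
                              replicates = 3,
                              n_cells = 6,
                              mean_radius = 5000,
                              irregularity = 0.25,
                              cluster = cluster_params(),
                              background_intensity = 15,
                              csr_intensity = 15,
                              disruption = disruption_params(),
                              aie = aie_params(),
                              conventional_brightness = 150,
                              labeling_efficiency = 0.9,
                              dye_mode = c("single", "poisson_dar"),
                              dar = 1.35,
                              optics = optics_params(),
                              segmentation = segmentation_params(),
                              master_seed = 1) {
  cell_model <- match.arg(cell_model)
  dye_mode <- match.arg(dye_mode)
  if (!is.numeric(doses) || any(doses < 0) || !any(doses == 0))
    stop("`doses` must be nonnegative and include 0 (untreated control)")
  if (!is.numeric(times) || any(times < 0))
    stop("`times` must be nonnegative")
  stopifnot(replicates >= 1, n_cells >= 1)
  stopifnot(inherits(cluster, "cluster_params"),
            inherits(disruption, "disruption_params"),
            inherits(aie, "aie_params"),
            inherits(optics, "optics_params"),
            inherits(segmentation, "segmentation_params"))
  check_scalar(background_intensity, "background_intensity", lower = 0)
  check_scalar(csr_intensity, "csr_intensity", lower = 0)
  check_scalar(conventional_brightness, "conventional_brightness",
               lower = 0, lower_open = TRUE)
  check_scalar(labeling_efficiency, "labeling_efficiency",
               lower = 0, upper = 1, lower_open = TRUE)
  # the largest possible footprint must fit in the frame with a PSF margin
  extent <- optics$image_shape * optics$pixel_size
  need <- 2 * mean_radius * (1 + irregularity) + 4 * optics$psf_sigma
  if (any(extent < need))
    stop(sprintf("image_shape too small: footprint needs %.0f nm, frame is %.0f x %.0f nm",
                 need, extent[1], extent[2]))
  structure(list(cell_model = cell_model, doses = sort(unique(doses)),
                 times = sort(unique(times)), replicates = as.integer(replicates),
                 n_cells = as.integer(n_cells), mean_radius = mean_radius,
                 irregularity = irregularity, cluster = cluster,
                 background_intensity = background_intensity,
                 csr_intensity = csr_intensity, disruption = disruption,
                 aie = aie, conventional_brightness = conventional_brightness,
                 labeling_efficiency = labeling_efficiency,
                 dye_mode = dye_mode, dar = dar, optics = optics,
                 segmentation = segmentation,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %s cells; doses {%s} ug/mL x times {%s} h x %d replicates, %d cells/well\n",
              x$cell_model, paste(x$doses, collapse = ", "),
              paste(x$times, collapse = ", "), x$replicates, x$n_cells))
  invisible(x)
}

simulate_cell_well <- function(config, time, replicate, cell, master_seed) {
  fp <- sample_cell_footprint(
    derive_seed(master_seed, "footprint", time, replicate, cell),
    config$mean_radius, config$irregularity)
  field_seed <- derive_seed(master_seed, "field", time, replicate, cell)
  field <- if (config$cell_model == "clustered") {
    cl <- sample_receptors_clustered(fp, config$cluster, field_seed)
    bg <- sample_receptors_csr(
      fp, config$background_intensity,
      derive_seed(master_seed, "bgfield", time, replicate, cell),
      hardcore = 0)
    # dispersed pool thinned against the clusters so the merged field still
    # respects the hard-core distance
    pos <- rbind(cl$positions, bg$positions)
    keep <- enforce_hardcore(pos, config$cluster$hardcore)
    receptor_field(pos[keep, , drop = FALSE],
                   c(cl$cluster_id, bg$cluster_id)[keep],
                   fp, config$cluster$hardcore)
  } else {
    sample_receptors_csr(fp, config$csr_intensity, field_seed,
                         config$cluster$hardcore)
  }
  list(footprint = fp, field = field,
       disrupt_seed = derive_seed(master_seed, "disrupt", time, replicate, cell),
       label_seed_aie = derive_seed(master_seed, "label-aie", time, replicate, cell),
       label_seed_conv = derive_seed(master_seed, "label-conv", time, replicate, cell))
}

#' Run a full simulated disruption experiment
#'
#' Simulates every well of the configured plate: for each exposure time,
#' replicate and cell, a footprint and receptor field are generated, the
#' disruption model is applied at each dose, both dye channels (proximity
#' gated and conventional) are emitted and rendered, the cell area is
#' segmented on the conventional channel (which is insensitive to
#' clustering, so the mask does not depend on the treatment effect), and
#' masked mean intensity and SNR are quantified per channel. Wells pool
#' their cells area-weighted; the well table is then normalized to the
#' untreated controls.
#'
#' Within a replicate, the footprint, receptor field, labeling, and the
#' disruption uniforms are drawn from seed streams that do not involve the
#' dose, so the dose series of one replicate "treats" the same virtual
#' cells (common random numbers). Every seed is a deterministic hash of
#' the master seed and a stage label (see [derive_seed()]), making any
#' single well reproducible in isolation.
#'
#' @param config an [experiment_config()].
#' @param master_seed integer; defaults to `config$master_seed`.
#' @return an `aie_experiment` object: `wells` (one row per dye x dose x
#'   time x replicate), `cells` (per-cell rows), `table` (the normalized
#'   [normalize_to_control()] table), `config`, `master_seed`.
#' @export
run_experiment <- function(config, master_seed = config$master_seed) {
  stopifnot(inherits(config, "experiment_config"))
  extent <- config$optics$image_shape * config$optics$pixel_size
  cell_rows <- list()
  for (time in config$times) for (rep in seq_len(config$replicates)) {
    for (cell in seq_len(config$n_cells)) {
      cw <- simulate_cell_well(config, time, rep, cell, master_seed)
      offset <- (extent - cw$footprint$bounding_box) / 2
      for (dose in config$doses) {
        fd <- apply_disruption(cw$field, dose, time, config$disruption,
                               cw$disrupt_seed)
        ems <- list(
          AIE = aie_emission(fd, config$aie, config$labeling_efficiency,
                             cw$label_seed_aie, config$dye_mode, config$dar),
          conventional = conventional_emission(
            fd, config$conventional_brightness, config$labeling_efficiency,
            cw$label_seed_conv, config$dye_mode, config$dar))
        imgs <- lapply(names(ems), function(dye)
          render_image(ems[[dye]], config$optics, noise_on = TRUE,
                       rng_seed = derive_seed(master_seed, "noise", dye,
                                              time, rep, cell, dose),
                       offset = offset))
        names(imgs) <- names(ems)
        mask <- segment_cells(imgs$conventional, config$segmentation)
        if (mask$area_px == 0)
          stop(sprintf("segmentation found no cell (time=%g rep=%d cell=%d dose=%g)",
                       time, rep, cell, dose))
        for (dye in names(imgs)) {
          q <- mean_masked_intensity(imgs[[dye]], mask)
          cell_rows[[length(cell_rows) + 1L]] <- data.frame(
            cell_model = config$cell_model, dye = dye, dose = dose,
            time = time, replicate = rep, cell = cell,
            sum_intensity = q$sum_intensity, area_px = q$area_px,
            mean_intensity = q$mean_intensity,
            snr = compute_snr(imgs[[dye]], mask))
        }
      }
    }
  }
  cells <- do.call(rbind, cell_rows)
  wells <- stats::aggregate(
    cbind(sum_intensity, area_px, snr) ~ cell_model + dye + dose + time + replicate,
    data = cells, FUN = sum)
  wells$snr <- wells$snr / config$n_cells  # sum -> mean over cells
  wells$mean_intensity <- wells$sum_intensity / wells$area_px
  wells <- wells[order(wells$dye, wells$time, wells$dose, wells$replicate), ]
  rownames(wells) <- NULL
  structure(list(wells = wells, cells = cells,
                 table = normalize_to_control(wells),
                 config = config, master_seed = as.integer(master_seed)),
            class = "aie_experiment")
}

#' @export
print.aie_experiment <- function(x, ...) {
  cat(sprintf("<aie_experiment> %s model, master seed %d: %d wells (%d cells simulated)\n",
              x$config$cell_model, x$master_seed, nrow(x$wells),
              nrow(x$cells) / length(unique(x$cells$dye)) / length(x$config$doses)))
  print(x$table)
  invisible(x)
}

#' @export
summary.aie_experiment <- function(object, ...) {
  tab <- object$table
  cat("Simulated cluster-disruption experiment\n")
  print(object$config)
  for (dye in unique(tab$dye)) {
    sub <- tab[tab$dye == dye & tab$time == max(tab$time), ]
    cat(sprintf("  %s channel at %g h: mean_norm %s across doses {%s}\n",
                dye, max(tab$time),
                paste(sprintf("%.2f", sub$mean_norm), collapse = " -> "),
                paste(sub$dose, collapse = ", ")))
  }
  invisible(object)
}

#' @export
plot.aie_experiment <- function(x, ...) {
  tab <- x$table
  dyes <- unique(tab$dye)
  times <- unique(tab$time)
  old <- graphics::par(mfrow = c(1, length(dyes)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (dye in dyes) {
    sub <- tab[tab$dye == dye, ]
    plot(NA, xlim = range(pmax(sub$dose, min(sub$dose[sub$dose > 0]) / 10)),
         ylim = range(c(sub$mean_norm - sub$sd_norm,
                        sub$mean_norm + sub$sd_norm), na.rm = TRUE),
         log = "x", xlab = "dose (ug/mL)", ylab = "normalized mean intensity",
         main = dye)
    for (i in seq_along(times)) {
      s <- sub[sub$time == times[i], ]
      d <- pmax(s$dose, min(sub$dose[sub$dose > 0]) / 10)
      graphics::lines(d, s$mean_norm, type = "b", col = i, pch = 16)
      graphics::arrows(d, s$mean_norm - s$sd_norm, d, s$mean_norm + s$sd_norm,
                       angle = 90, code = 3, length = 0.02, col = i)
    }
    graphics::legend("bottomleft", legend = paste(times, "h"), col = seq_along(times),
                     lty = 1, pch = 16, bty = "n")
  }
  invisible(x)
}

#' Write an experiment's tables to CSV
#'
#' Writes `wells.csv` (per-well records) and `doseresponse.csv` (the
#' normalized table) with fixed 15-significant-digit formatting, so a
#' rerun with the same config and master seed reproduces the files
#' byte-for-byte.
#'
#' @param experiment an `aie_experiment`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
write_experiment_csv <- function(experiment, out_dir) {
  stopifnot(inherits(experiment, "aie_experiment"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fmt <- function(df) {
    for (nm in names(df)) if (is.numeric(df[[nm]]))
      df[[nm]] <- formatC(df[[nm]], digits = 15, format = "g")
    df
  }
  paths <- c(wells = file.path(out_dir, "wells.csv"),
             table = file.path(out_dir, "doseresponse.csv"))
  write.csv(fmt(experiment$wells), paths["wells"], row.names = FALSE, quote = FALSE)
  write.csv(fmt(as.data.frame(experiment$table)), paths["table"],
            row.names = FALSE, quote = FALSE)
  invisible(paths)
}
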