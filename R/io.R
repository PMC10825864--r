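#' Write / read a widefield image as TIFF
#'
#' Images are stored as single-channel TIFF, either 32-bit samples
#' (`"float32"`, the default; the writer passes values through single
#' precision, so a round trip agrees to about one part in 10^7) or 16-bit
#' unsigned (`"uint16"`, quantised to 65535 levels). TIFF stores values in
#' `[0, 1]`, so pixels are divided by a power-of-two scale factor chosen
#' from the image maximum; the scale and the pixel size are recorded in a
#' JSON sidecar (`<path>.json`) and restored on read.
#'
#' @param image a [micro_image()].
#' @param path TIFF file path.
#' @param bits `"float32"` or `"uint16"`.
#' @return invisibly, `path`.
#' @rdname image_io
#' @export
write_image <- function(image, path, bits = c("float32", "uint16")) {
  stopifnot(inherits(image, "micro_image"))
  bits <- match.arg(bits)
  mx <- max(image$pixels)
  scale <- if (mx > 1) 2^ceiling(log2(mx)) else 1
  tiff::writeTIFF(image$pixels / scale, path,
                  bits.per.sample = if (bits == "float32") 32L else 16L)
  jsonlite::write_json(
    list(pixel_size_nm = image$pixel_size, scale = scale, bits = bits),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param pixel_size pixel size in nm, required when no sidecar is found.
#' @return `read_image()` returns a [micro_image()].
#' @rdname image_io
#' @export
read_image <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  px <- tiff::readTIFF(path, info = TRUE)
  if (length(dim(px)) != 2)
    stop("unsupported format: only single-channel grayscale TIFF is supported ",
         "(got ", paste(dim(px), collapse = "x"), ")")
  scale <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    scale <- meta$scale
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size_nm
  }
  if (is.null(pixel_size))
    stop("`pixel_size` is required when the image has no metadata sidecar")
  micro_image(matrix(as.numeric(px) * scale, nrow(px), ncol(px)), pixel_size)
}

#' Read an experiment configuration from YAML
#'
#' The YAML mirrors [experiment_config()]: scalar options at the top
#' level, and nested mappings `cluster`, `disruption`, `aie`, `optics`,
#' `segmentation` passed to the corresponding parameter constructors.
#' Unknown keys at any level are an error naming the offending keys, so a
#' typo cannot silently fall back to a default. An annotated example ships
#' in `system.file("extdata", "experiment_config.yaml", package = "aieclust")`.
#'
#' @param path YAML file path.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  experiment_config_from_list(yaml::read_yaml(path))
}

#' @rdname read_experiment_config
#' @param config a named list with the structure described above.
#' @export
experiment_config_from_list <- function(config) {
  if (!is.list(config)) stop("config must be a named list / YAML mapping")
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(given, allowed)
    if (length(bad) > 0)
      stop(sprintf("unknown config key%s in %s: %s",
                   if (length(bad) > 1) "s" else "", where,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  check_keys(names(config), names(formals(experiment_config)), "config")
  ctors <- list(cluster = cluster_params, disruption = disruption_params,
                aie = aie_params, optics = optics_params,
                segmentation = segmentation_params)
  for (key in names(ctors)) {
    if (!is.null(config[[key]]) && !inherits(config[[key]], paste0(key, "_params"))) {
      check_keys(names(config[[key]]), names(formals(ctors[[key]])), key)
      config[[key]] <- do.call(ctors[[key]], config[[key]])
    }
  }
  do.call(experiment_config, config)
}

#' Generate the deterministic fixture suite
#'
#' Writes a small, fully programmatic set of test images with ground-truth
#' sidecar CSVs: a bright disk (known centre/radius/area), two disjoint
#' blobs (known component count), a perfectly correlated channel pair
#' (`B = 2A + 5`) and an anti-correlated pair, and a 3-dose
#' mini-experiment's well and dose-response tables. Identical seeds
#' produce byte-identical files.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed.
#' @return invisibly, the vector of files written.
#' @export
make_fixtures <- function(out_dir, seed = 1) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  }
  if (file.access(out_dir, 2) != 0) stop("directory not writable: ", out_dir)
  p <- function(...) file.path(out_dir, ...)

  disk_image <- function(nr, nc, cx, cy, r, fg, bg) {
    d2 <- outer(seq_len(nr) - cy, seq_len(nc) - cx,
                function(i, j) i^2 + j^2)
    matrix(ifelse(d2 <= r^2, fg, bg), nr, nc)
  }
  # single disk + analytic ground truth
  disk <- disk_image(64, 64, 32.5, 32.5, 12, 100, 10)
  write_image(micro_image(disk, 325), p("disk.tif"))
  write.csv(data.frame(center_row = 32.5, center_col = 32.5, radius_px = 12,
                       area_analytic_px = pi * 12^2, area_px = sum(disk == 100),
                       foreground = 100, background = 10),
            p("disk_truth.csv"), row.names = FALSE, quote = FALSE)
  # two disjoint blobs
  blobs <- pmax(disk_image(64, 64, 18, 18, 8, 100, 10),
                disk_image(64, 64, 46, 46, 8, 100, 10))
  write_image(micro_image(blobs, 325), p("two_blobs.tif"))
  write.csv(data.frame(n_components = 2, radius_px = 8),
            p("two_blobs_truth.csv"), row.names = FALSE, quote = FALSE)
  # correlated / anti-correlated channel pairs
  a <- with_seed(derive_seed(seed, "fixture", "channels"),
                 matrix(runif(64 * 64, 10, 100), 64, 64))
  write_image(micro_image(a, 325), p("channel_a.tif"))
  write_image(micro_image(2 * a + 5, 325), p("channel_b_corr.tif"))
  write_image(micro_image(max(a) - a, 325), p("channel_b_anticorr.tif"))
  write.csv(data.frame(pair = c("corr", "anticorr"), pcc = c(1, -1)),
            p("channels_truth.csv"), row.names = FALSE, quote = FALSE)
  # 3-dose mini experiment
  cfg <- experiment_config(doses = c(0, 1, 100), times = 24, replicates = 2,
                           n_cells = 2, master_seed = derive_seed(seed, "fixture", "mini"))
  write_experiment_csv(run_experiment(cfg), out_dir)

  files <- c("disk.tif", "disk_truth.csv", "two_blobs.tif", "two_blobs_truth.csv",
             "channel_a.tif", "channel_b_corr.tif", "channel_b_anticorr.tif",
             "channels_truth.csv", "wells.csv", "doseresponse.csv")
  invisible(p(files))
}
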