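#' Write a count image pair as multi-page TIFF with JSON sidecar
#'
#' Stores the pair as a two-page 16-bit unsigned TIFF (page 1 = INT, page 2
#' = G2) and the acquisition metadata — gate (s, W, T in ns), frame budget
#' F, bit depth, delays for scans, seed, software version — in a JSON
#' sidecar at `<path>.json`. Integer counts round-trip losslessly.
#'
#' @param pair [count_image_pair()].
#' @param path Output TIFF path (sidecar written next to it).
#' @param meta Named list merged into the sidecar (e.g. `seed`, `delays`).
#' @return `path`, invisibly.
#' @export
write_pair <- function(pair, path, meta = list()) {
  stopifnot(inherits(pair, "count_image_pair"))
  if (max(pair$int_) > 65535) {
    stop("counts exceed the 16-bit storage range", call. = FALSE)
  }
  pages <- list(pair$int_ / 65535, pair$g2 / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  sidecar <- modifyList(list(
    gate_offset_ns = pair$gate$s,
    gate_width_ns = pair$gate$W,
    period_ns = pair$gate$T,
    frames_per_image = pair$F,
    page_order = c("INT", "G2"),
    units = list(time = "ns", counts = "frames"),
    software = paste0("snapflim ",
                      as.character(utils::packageVersion("snapflim")))
  ), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a count image pair written by [write_pair()]
#'
#' @param path TIFF path; the sidecar `<path>.json` must exist.
#' @return List with `pair` (a [count_image_pair()]) and `meta` (the parsed
#'   sidecar).
#' @export
read_pair <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path)) {
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  }
  if (!file.exists(sidecar_path)) {
    stop(sprintf("missing JSON sidecar: %s", sidecar_path), call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  required <- c("gate_offset_ns", "gate_width_ns", "period_ns",
                "frames_per_image")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    stop(sprintf("sidecar %s is missing required keys: %s", sidecar_path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) != 2L) {
    stop(sprintf("%s: expected 2 pages (INT, G2), found %d", path,
                 length(pages)), call. = FALSE)
  }
  gate <- gate_window(meta$gate_offset_ns, meta$gate_width_ns,
                      meta$period_ns)
  pair <- tryCatch(
    count_image_pair(pages[[2]], pages[[1]], meta$frames_per_image, gate),
    error = function(e) {
      stop(sprintf("%s: %s", path, conditionMessage(e)), call. = FALSE)
    })
  list(pair = pair, meta = meta)
}

#' Write a lifetime map as 32-bit TIFF
#'
#' Page 1 is the lifetime scaled by `tau_scale_ns` (invalid pixels 0), page
#' 2 the validity mask (1 valid, 0 invalid); a JSON sidecar carries the
#' scale and summary statistics (mean, sd, valid-pixel count). TIFF samples
#' are stored in `[0, 1]` at 32 bits, so the scale factor (recorded in the
#' sidecar) restores nanoseconds on read to ~1e-9 ns.
#'
#' @param map [estimate_map()] result.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_lifetime_map <- function(map, path) {
  stopifnot(inherits(map, "lifetime_map"))
  tau <- map$tau
  tau[!map$valid] <- 0
  tau_scale <- max(tau, 1)
  tiff::writeTIFF(list(tau / tau_scale, map$valid * 1), path,
                  bits.per.sample = 32, reduce = FALSE)
  summary <- list(
    tau_scale_ns = tau_scale,
    mean_tau_ns = mean(map$tau[map$valid]),
    sd_tau_ns = stats::sd(map$tau[map$valid]),
    n_valid = sum(map$valid),
    n_masked = map$n_masked,
    valid_fraction = mean(map$valid),
    units = list(tau = "ns")
  )
  jsonlite::write_json(summary, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a YAML run configuration
#'
#' Validates the block structure of a run configuration and rejects unknown
#' top-level keys with a clear message.
#'
#' @param path YAML file.
#' @return Named list of configuration blocks.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("scene", "sensor", "gate", "estimator", "dynamics",
             "output", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown configuration keys: %s (known: %s)",
                 paste(unknown, collapse = ", "),
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  cfg
}
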