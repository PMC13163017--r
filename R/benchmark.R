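#' Serialize / load a deployable model bundle
#'
#' A bundle is the single-file artifact shipped to the edge device: the
#' fitted model plus the scaler, selected-feature indices, schema and label
#' order needed to reproduce inference exactly. Its on-disk size is what
#' the benchmark reports as footprint. Bundles are stored uncompressed,
#' the deployment convention of the reference ML stacks (and the one under
#' which published footprint figures such as a ~0.6 MB MLP pipeline are
#' comparable); compression would hide the memory the artifact actually
#' occupies once loaded.
#'
#' @param model a trained `bleat_model`.
#' @param path output path.
#' @param scaler optional `bleat_scaler`.
#' @param selected optional integer vector of selected feature indices.
#' @param schema optional `bleat_schema`.
#' @return `path` (save) or the bundle list (load).
#' @export
save_bundle <- function(model, path, scaler = NULL, selected = NULL,
                        schema = NULL) {
  stopifnot(inherits(model, "bleat_model"))
  saveRDS(list(model = model, scaler = scaler, selected = selected,
               schema = schema, labels = model$labels),
          path, compress = FALSE)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop("no such bundle: ", path)
  readRDS(path)
}

#' Inference latency and artifact footprint benchmark
#'
#' Latency is the median over repeats of the mean per-sample wall time of a
#' full-probe prediction pass (warm-up passes excluded); footprint is the
#' size of the serialized bundle on disk. Absolute values are hardware- and
#' serialization-dependent and are report outputs only — tests assert
#' orderings, never thresholds.
#'
#' @param m a trained `bleat_model`.
#' @param X_probe probe feature matrix (non-empty).
#' @param repeats timed passes (>= 3).
#' @param warmup untimed warm-up passes.
#' @param scaler,selected,schema forwarded to [save_bundle()] so the
#'   footprint matches the deployable artifact.
#' @return An object of class `bleat_bench`: `latency_ms_per_sample`,
#'   `latency_ms_std`, `footprint_mb`, `repeats`, `batch`.
#' @export
benchmark_model <- function(m, X_probe, repeats = 10L, warmup = 2L,
                            scaler = NULL, selected = NULL, schema = NULL) {
  stopifnot(inherits(m, "bleat_model"))
  X_probe <- as.matrix(X_probe)
  if (nrow(X_probe) == 0L) stop("probe set is empty")
  if (repeats < 3L) stop("repeats must be >= 3")
  for (i in seq_len(warmup)) predict(m, X_probe)
  # repeat the pass inside one timing until it is measurable at the wall
  # clock's resolution, so fast models do not report zero latency
  inner <- 1L
  repeat {
    t0 <- proc.time()[["elapsed"]]
    for (i in seq_len(inner)) predict(m, X_probe)
    if (proc.time()[["elapsed"]] - t0 >= 0.05 || inner >= 1024L) break
    inner <- inner * 4L
  }
  times <- numeric(repeats)
  for (r in seq_len(repeats)) {
    t0 <- proc.time()[["elapsed"]]
    for (i in seq_len(inner)) predict(m, X_probe)
    times[r] <- (proc.time()[["elapsed"]] - t0) * 1000 /
      (nrow(X_probe) * inner)
  }
  tmp <- tempfile(fileext = ".bundle")
  on.exit(unlink(tmp))
  save_bundle(m, tmp, scaler = scaler, selected = selected, schema = schema)
  structure(list(latency_ms_per_sample = stats::median(times),
                 latency_ms_std = stats::sd(times),
                 footprint_mb = file.size(tmp) / 1e6,
                 repeats = repeats, batch = nrow(X_probe)),
            class = "bleat_bench")
}

#' @export
print.bleat_bench <- function(x, ...) {
  cat(sprintf(
    "latency %.4f ms/sample (sd %.4f over %d repeats, batch %d); footprint %.3f MB\n",
    x$latency_ms_per_sample, x$latency_ms_std, x$repeats, x$batch,
    x$footprint_mb))
  invisible(x)
}
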