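#' The canonical ordered feature schema
#'
#' `table1` mode defines the 156-descriptor contract: 5 temporal/energy
#' statistics, 3 time-evolution statistics, 40 MFCC means, 40 delta means,
#' 40 delta-delta means, 20 spectral-shape statistics (including 14
#' contrast values), 2 complexity values (entropy, flatness), 2 bioacoustic
#' indices, and 4 fundamental-frequency statistics. `extended` mode appends
#' the 40 per-coefficient standard deviations of each cepstral block
#' (276 entries total) so that tokens such as `mfcc_std_5`, used in
#' importance analyses, exist as first-class features.
#'
#' @param mode `"table1"` (156 features) or `"extended"` (276).
#' @param n_mfcc cepstral coefficients per block (default 40).
#' @return An object of class `bleat_schema`: data frame `entries` with
#'   columns `name`, `category`, `source`, plus `mode`.
#' @export
default_schema <- function(mode = c("table1", "extended"), n_mfcc = 40L) {
  mode <- match.arg(mode)
  n_mfcc <- as.integer(n_mfcc)
  idx <- seq_len(n_mfcc) - 1L
  ent <- function(name, category, source)
    data.frame(name = name, category = category, source = source,
               stringsAsFactors = FALSE)
  entries <- rbind(
    ent(c("rms_mean", "rms_std", "zcr_mean", "zcr_std", "autocorr_peak"),
        "temporal_energy", "temporal_energy_features"),
    ent(c("flux_mean", "flux_std", "temporal_centroid"),
        "time_evolution", "time_evolution_features"),
    ent(paste0("mfcc_mean_", idx), "mfcc", "cepstral_stats"),
    ent(paste0("delta_mean_", idx), "delta", "cepstral_stats"),
    ent(paste0("delta2_mean_", idx), "delta2", "cepstral_stats"),
    ent(c("centroid_mean", "centroid_std", "bandwidth_mean",
          "bandwidth_std", "rolloff_mean", "rolloff_std",
          paste0("contrast_mean_", 0:6), paste0("contrast_std_", 0:6)),
        "spectral_shape", "spectral_shape_features"),
    ent(c("entropy", "flatness"), "complexity", "spectral_shape_features"),
    ent(c("aci", "bioacoustic_index"), "bioacoustic", "aci_bio"),
    ent(c("f0_mean", "f0_max", "f0_std", "f0_slope"), "pitch", "f0_stats"))
  if (mode == "extended") {
    entries <- rbind(entries,
      ent(paste0("mfcc_std_", idx), "mfcc", "cepstral_stats"),
      ent(paste0("delta_std_", idx), "delta", "cepstral_stats"),
      ent(paste0("delta2_std_", idx), "delta2", "cepstral_stats"))
  }
  stopifnot(!anyDuplicated(entries$name))
  structure(list(entries = entries, mode = mode, n_mfcc = n_mfcc),
            class = "bleat_schema")
}

#' @export
print.bleat_schema <- function(x, ...) {
  cat(sprintf("<bleat_schema: %s mode, %d features>\n", x$mode,
              nrow(x$entries)))
  print(table(x$entries$category))
  invisible(x)
}

#' @export
length.bleat_schema <- function(x) nrow(x$entries)

#' Extract the full feature vector for one clip
#'
#' Runs every descriptor family once on a resampled, duration-standardized
#' waveform and assembles the values in schema order. Extraction is a pure,
#' deterministic function of (samples, rate, schema, spec); any non-finite
#' value surviving the sentinel rules raises an error naming the feature.
#'
#' @param w a [waveform()], already resampled and standardized.
#' @param schema a [default_schema()].
#' @param spec a [frame_spec()].
#' @param fmin,fmax pYIN search range (Hz).
#' @return Named numeric vector aligned with the schema.
#' @export
extract_features <- function(w, schema = default_schema(),
                             spec = frame_spec(), fmin = 65, fmax = 2093) {
  stopifnot(inherits(w, "bleat_wave"), inherits(schema, "bleat_schema"))
  S <- stft(w, spec)
  which_stat <- if (schema$mode == "extended") "mean_and_std" else "mean"
  C0 <- mfcc(S, n_coeff = schema$n_mfcc)
  C1 <- cepstral_delta(C0, 1L)
  C2 <- cepstral_delta(C0, 2L)
  vals <- c(
    temporal_energy_features(w, spec),
    time_evolution_features(S),
    cepstral_stats(C0, which_stat, "mfcc"),
    cepstral_stats(C1, which_stat, "delta"),
    cepstral_stats(C2, which_stat, "delta2"),
    spectral_shape_features(S),
    aci = aci(S),
    bioacoustic_index = bioacoustic_index(S),
    f0_stats(pyin_track(w, fmin = fmin, fmax = fmax, spec = spec)))
  missing <- setdiff(schema$entries$name, names(vals))
  if (length(missing))
    stop("extraction did not produce feature(s): ",
         paste(missing, collapse = ", "))
  out <- vals[schema$entries$name]
  bad <- !is.finite(out)
  if (any(bad))
    stop("non-finite feature value(s): ",
         paste(names(out)[bad], collapse = ", "))
  out
}

#' Extract a labeled feature table from a clip collection
#'
#' Applies resampling, duration standardization, and [extract_features()]
#' to every clip.
#'
#' @param waves list of [waveform()]s.
#' @param labels character class labels, one per clip.
#' @param clip_ids optional clip identifiers.
#' @param schema a [default_schema()].
#' @param rate pipeline sampling rate (Hz, default 22050).
#' @param duration_s standardized duration (s).
#' @param spec a [frame_spec()].
#' @return A list of class `bleat_featureset`: `X` (clips x features
#'   matrix), `y` (labels), `feature_names`, `clip_ids`.
#' @export
extract_corpus_features <- function(waves, labels, clip_ids = NULL,
                                    schema = default_schema(),
                                    rate = 22050L, duration_s = 2.0,
                                    spec = frame_spec()) {
  stopifnot(length(waves) == length(labels))
  if (is.null(clip_ids)) clip_ids <- sprintf("clip_%04d", seq_along(waves))
  X <- matrix(NA_real_, nrow = length(waves), ncol = length(schema),
              dimnames = list(clip_ids, schema$entries$name))
  for (i in seq_along(waves)) {
    w <- standardize_duration(resample_wave(waves[[i]], rate), duration_s)
    X[i, ] <- extract_features(w, schema, spec)
  }
  structure(list(X = X, y = as.character(labels),
                 feature_names = schema$entries$name, clip_ids = clip_ids),
            class = "bleat_featureset")
}

#' Write / read a feature table as CSV
#'
#' The CSV carries one row per clip with `clip_id` and `label` columns
#' followed by the schema-ordered feature columns.
#'
#' @param fs a `bleat_featureset`.
#' @param path CSV path.
#' @return `path` (write) or a `bleat_featureset` (read).
#' @export
write_feature_table <- function(fs, path) {
  stopifnot(inherits(fs, "bleat_featureset"))
  df <- data.frame(clip_id = fs$clip_ids, label = fs$y,
                   fs$X, check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("clip_id", "label") %in% names(df)))
  feat <- setdiff(names(df), c("clip_id", "label"))
  X <- as.matrix(df[, feat, drop = FALSE])
  rownames(X) <- df$clip_id
  structure(list(X = X, y = df$label, feature_names = feat,
                 clip_ids = df$clip_id), class = "bleat_featureset")
}

#' Serialize a schema to JSON
#' @param schema a [default_schema()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_schema_json <- function(schema, path) {
  jsonlite::write_json(list(mode = schema$mode, n_mfcc = schema$n_mfcc,
                            entries = schema$entries),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
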