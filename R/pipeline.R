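# Study manifest handling and the seeded end-to-end pipeline.
#
# The pipeline mirrors the sensor-space analysis (preprocess -> Welch ->
# band power -> MSI -> t-tests / RM-ANOVA) followed by the source-space
# analysis (wMNE projection -> per-vertex MSI -> paired sign-flip cluster
# permutation of post vs pre session maps). All stage seeds derive from the
# single config seed via split_seed().

#' Read / write a study manifest
#'
#' CSV with columns `subject`, `session`, `condition`, `path` and optional
#' `role` (`action` / `rest`, inferred from the condition label when
#' absent). (subject, session, condition) triples must be unique.
#'
#' @param path CSV path.
#' @return data.frame manifest.
#' @export
read_manifest <- function(path) {
  assert_that(file.exists(path), "parse_error",
              sprintf("manifest not found: %s", path))
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("subject", "session", "condition", "path") %in% names(m)),
              "parse_error", "manifest needs subject, session, condition, path")
  key <- paste(m$subject, m$session, m$condition)
  assert_that(!anyDuplicated(key), "parse_error",
              "duplicate (subject, session, condition) rows in manifest")
  if (is.null(m$role)) {
    m$role <- ifelse(is_rest_condition(m$condition), "rest", "action")
  }
  m
}

#' Write a simulated study to disk
#'
#' Writes every recording (internal container or EDF), the montage, and a
#' manifest CSV binding them together.
#'
#' @param study result of [simulate_study()].
#' @param model the `source_model` used (for the montage file).
#' @param dir output directory (created if needed).
#' @param format `"internal"` (lossless) or `"edf"` (16-bit, lossy by
#'   format).
#' @return the manifest path, invisibly.
#' @export
write_study <- function(study, model, dir, format = c("internal", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "internal") "eegc" else "edf"
  idx <- study$index
  idx$path <- file.path(dir, sprintf("%s_%s_%s.%s", idx$subject, idx$session,
                                     idx$condition, ext))
  for (i in seq_len(nrow(idx))) {
    rec <- study$recordings[[idx$position[i]]]
    if (format == "internal") write_eegc(rec, idx$path[i])
    else write_edf(rec, idx$path[i])
  }
  write_montage(model$channels, file.path(dir, "montage.txt"))
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(idx[c("subject", "session", "condition", "path", "role")],
                   mpath, row.names = FALSE)
  invisible(mpath)
}

#' Pipeline configuration
#'
#' Defaults reproduce the standard analysis constants: 2-s action-clip /
#' 10-s resting-block trims, 2-s Hamming windows with 50% overlap, 8-13 Hz
#' mu band, non-biological-motion baseline, the C3/C4/Cz electrode set,
#' wMNE with identity noise covariance (SNR-3 regularisation, depth 0.5),
#' and 1,000 sign-flip permutations at a two-sided cluster-forming p = 0.05.
#'
#' @param trim_action,trim_rest trim seconds for action clips / rest blocks.
#' @param window_sec,overlap Welch parameters.
#' @param band mu band `c(lo, hi)` in Hz.
#' @param baseline_condition baseline label for the MSI ratio.
#' @param electrodes sensor set averaged for the group tests.
#' @param lambda2,depth_gamma,snr inverse parameters (see [build_wmne()]).
#' @param n_perm,cluster_alpha permutation parameters.
#' @param seed global pipeline seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(trim_action = 2, trim_rest = 10, window_sec = 2,
                            overlap = 0.5, band = c(8, 13),
                            baseline_condition = "balls",
                            electrodes = c("C3", "C4", "Cz"),
                            lambda2 = "auto", depth_gamma = 0.5, snr = 3,
                            n_perm = 1000, cluster_alpha = 0.05, seed = 1L) {
  structure(list(trim_action = trim_action, trim_rest = trim_rest,
                 window_sec = window_sec, overlap = overlap, band = band,
                 baseline_condition = baseline_condition,
                 electrodes = electrodes, lambda2 = lambda2,
                 depth_gamma = depth_gamma, snr = snr, n_perm = n_perm,
                 cluster_alpha = cluster_alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

# band power per location for one recording, optionally also in source space
segment_powers <- function(rec, config, kernel = NULL) {
  trim <- if (is_rest_condition(rec$condition)) config$trim_rest else config$trim_action
  seg <- preprocess_condition(rec, trim)
  out <- list()
  sp <- welch_psd(seg, config$window_sec, config$overlap)
  out$sensor <- band_power(sp, config$band[1], config$band[2])$power
  if (!is.null(kernel)) {
    ss <- welch_psd(project_segment(seg, kernel), config$window_sec, config$overlap)
    out$source <- band_power(ss, config$band[1], config$band[2])$power
  }
  out
}

powers_long <- function(rows, what) {
  do.call(rbind, lapply(rows, function(r) {
    p <- r$powers[[what]]
    data.frame(subject = r$subject, session = r$session,
               condition = r$condition, location = names(p),
               power = unname(p), stringsAsFactors = FALSE)
  }))
}

#' Run the full analysis pipeline
#'
#' Takes either an in-memory study (`study` from [simulate_study()]) or a
#' manifest of files on disk, and produces the sensor-space MSI table with
#' its t-tests and RM-ANOVA, and (when a head model is supplied) the
#' source-space MSI table and the post-vs-pre cluster permutation contrast
#' per condition. Deterministic given `config$seed`.
#'
#' @param study list with `recordings` and `index` (as from
#'   [simulate_study()]); alternative to `manifest`.
#' @param manifest path to a manifest CSV of recordings on disk.
#' @param config a `pipeline_config`.
#' @param model optional `source_model` enabling the source-space stages.
#' @param stages character subset of `c("sensor", "source")`.
#' @return list with `msi_sensor`, `ttests` (per session x condition),
#'   `anova`, and when source stages ran: `msi_source`, `clusters` (one
#'   `cluster_result` per condition), plus `config`, `config_hash`.
#' @export
run_pipeline <- function(study = NULL, manifest = NULL,
                         config = pipeline_config(), model = NULL,
                         stages = c("sensor", "source")) {
  assert_that(xor(is.null(study), is.null(manifest)), "invalid_input",
              "supply exactly one of study or manifest")
  if (!is.null(manifest)) {
    idx <- read_manifest(manifest)
    get_rec <- function(i) read_recording(idx$path[i])
  } else {
    idx <- study$index
    get_rec <- function(i) study$recordings[[idx$position[i]]]
  }
  assert_that(config$baseline_condition %in% idx$condition,
              "baseline_missing",
              sprintf("baseline condition '%s' absent from manifest",
                      config$baseline_condition))
  do_source <- "source" %in% stages && !is.null(model)
  kernel <- if (do_source)
    build_wmne(model, config$lambda2, config$depth_gamma, config$snr)

  video_conditions <- setdiff(unique(idx$condition[idx$role == "action"]),
                              character(0))
  rows <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (idx$role[i] == "rest") next    # resting blocks are not MSI inputs
    rec <- get_rec(i)
    rows[[i]] <- list(subject = idx$subject[i], session = idx$session[i],
                      condition = idx$condition[i],
                      powers = segment_powers(rec, config, kernel))
  }
  rows <- Filter(Negate(is.null), rows)

  sensor_pow <- powers_long(rows, "sensor")
  msi_sensor <- msi_table(sensor_pow, config$baseline_condition)

  # per-subject mean over the configured electrode set, per session x condition
  sel <- msi_sensor[msi_sensor$location %in% config$electrodes, ]
  agg <- NULL; ttests <- list(); anova <- NULL
  if (nrow(sel)) {
    agg <- stats::aggregate(msi ~ subject + session + condition, sel, mean)
    for (se in unique(agg$session)) for (co in unique(agg$condition)) {
      v <- agg$msi[agg$session == se & agg$condition == co]
      if (length(v) >= 2 && stats::sd(v) > 0) {
        ttests[[paste(se, co, sep = ".")]] <- msi_ttest_zero(v)
      }
    }
    if (length(unique(agg$session)) >= 2 && length(unique(agg$condition)) >= 2) {
      anova <- rm_anova(sel, dv = "msi", subject = "subject",
                        factors = c("session", "condition", "location"))
    }
  }

  out <- list(msi_sensor = msi_sensor, msi_group = agg, ttests = ttests,
              anova = anova, config = config, config_hash = config_hash(config))

  if (do_source) {
    source_pow <- powers_long(rows, "source")
    msi_source <- msi_table(source_pow, config$baseline_condition)
    out$msi_source <- msi_source
    sessions <- sort(unique(msi_source$session))
    if (setequal(sessions, c("pre", "post"))) sessions <- c("pre", "post")
    if (length(sessions) == 2) {
      out$clusters <- list()
      for (co in setdiff(unique(msi_source$condition), config$baseline_condition)) {
        D <- msi_difference_matrix(msi_source, co, sessions[1], sessions[2])
        out$clusters[[co]] <- permutation_test(
          D, model$adjacency, n_perm = config$n_perm,
          alpha_cluster = config$cluster_alpha,
          seed = split_seed(config$seed, paste0("perm/", co)))
      }
    }
  }
  out
}

#' Per-subject session-difference matrix from an MSI table
#'
#' Pivots a long MSI table into the subjects x locations matrix of
#' `session_b - session_a` differences for one condition (the input to
#' [permutation_test()]). `pre`/`post` sort so that alphabetical order is
#' (post, pre); pass sessions explicitly for the post-minus-pre contrast.
#'
#' @param msi long `msi_table`.
#' @param condition condition label to extract.
#' @param session_a,session_b the two session labels (difference is B - A).
#' @return subjects x locations numeric matrix.
#' @export
msi_difference_matrix <- function(msi, condition, session_a, session_b) {
  d <- msi[msi$condition == condition, ]
  pv <- function(se) {
    x <- d[d$session == se, ]
    m <- tapply(x$msi, list(x$subject, x$location), mean)
    m[, order(colnames(m)), drop = FALSE]
  }
  A <- pv(session_a); B <- pv(session_b)
  assert_that(identical(dimnames(A), dimnames(B)), "pairing_error",
              "sessions do not share subjects/locations")
  # restore numeric vertex order when labels are v001-style
  if (all(grepl("^v[0-9]+$", colnames(A)))) {
    o <- order(as.integer(sub("^v", "", colnames(A))))
    A <- A[, o, drop = FALSE]; B <- B[, o, drop = FALSE]
  }
  B - A
}
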