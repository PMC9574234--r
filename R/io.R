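#' Write tap and probe events as a BIDS-style events TSV
#'
#' Tab-separated, UTF-8, '.' decimal, `n/a` for missing values. Columns:
#' `onset`, `duration`, `trial_type` ("tap", "stimulus", "probe"),
#' `hand`, `block`, `condition`, `response`. Times are session-relative
#' seconds.
#'
#' @param session one subject's element of an `ftrsgt_session`
#'   (`session$subjects[[i]]`).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_events_tsv <- function(session, path) {
  taps <- session$taps
  blocks <- session$blocks
  onsets <- attr(blocks, "stim_onsets")
  stim <- data.frame(onset = unlist(onsets), duration = 0.075,
                     trial_type = "stimulus", hand = NA_character_,
                     block = rep(blocks$block,
                                 vapply(onsets, length, integer(1))),
                     condition = rep(blocks$condition,
                                     vapply(onsets, length, integer(1))),
                     response = NA_integer_)
  tap <- data.frame(onset = taps$time, duration = 0,
                    trial_type = "tap", hand = taps$hand,
                    block = taps$block,
                    condition = blocks$condition[taps$block],
                    response = NA_integer_)
  probes <- session$probes
  prb <- data.frame(onset = probes$probe_onset, duration = 6,
                    trial_type = "probe", hand = NA_character_,
                    block = probes$block, condition = probes$condition,
                    response = probes$response)
  ev <- rbind(stim, tap, prb)
  ev <- ev[order(ev$onset), ]
  ev_fmt <- ev
  for (cl in names(ev_fmt)) {
    v <- ev_fmt[[cl]]
    ev_fmt[[cl]] <- ifelse(is.na(v), "n/a",
                           if (is.numeric(v)) format(v, digits = 10,
                                                     scientific = FALSE,
                                                     trim = TRUE) else v)
  }
  utils::write.table(ev_fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a BIDS-style events TSV
#'
#' @param path TSV path with at least `onset`, `duration`, `trial_type`.
#' @return data.frame with typed columns, `n/a` mapped to NA; errors on
#'   missing required columns or unsorted onsets.
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, na.strings = "n/a",
                          stringsAsFactors = FALSE)
  req <- c("onset", "duration", "trial_type")
  miss <- setdiff(req, names(ev))
  if (length(miss))
    stop(sprintf("events file missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  if (is.unsorted(ev$onset)) stop("event onsets are not sorted")
  ev
}

#' Write / read a pupil trace as CSV (`time_s`, `pupil`)
#'
#' Missing samples are written as empty fields.
#'
#' @param trace a `pupil_trace`.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_pupil_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time, pupil = trace$size),
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_pupil_csv
#' @param fs sampling rate if not inferable from the time column.
#' @return for the reader: a `pupil_trace`.
#' @export
read_pupil_csv <- function(path, fs = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "pupil") %in% names(d)))
    stop("pupil CSV must have columns time_s, pupil")
  if (is.null(fs)) {
    dt <- stats::median(diff(d$time_s))
    fs <- 1 / dt
  }
  out <- list(time = d$time_s, size = d$pupil, fs = fs,
              mask = ifelse(is.na(d$pupil), 2L, 0L), events = NULL)
  class(out) <- "pupil_trace"
  out
}

#' Write / read a volume as NIfTI-1
#'
#' Thin wrappers around RNifti keeping the array + affine convention used
#' throughout the GLM module.
#'
#' @param x 3D/4D numeric array.
#' @param path `.nii` or `.nii.gz` path.
#' @param pixdim voxel sizes (mm / s), recycled to the array rank.
#' @return the path, invisibly.
#' @export
write_volume <- function(x, path, pixdim = 2) {
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- rep_len(pixdim, length(dim(x)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}

#' Run the synthetic end-to-end pipeline
#'
#' Orchestrates simulate -> behavior -> (optional) pupil -> probit on a
#' synthetic cohort and writes the declared artifacts (events TSVs, probe
#' feature CSV, model summary CSV, JSON manifest) under `out_dir`. Stages
#' already present on disk with a matching config hash are reused.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of `c("simulate", "behavior", "probit")`.
#' @param probit_args list of arguments passed to [run_model1()]
#'   (e.g. smaller `chains`/`iter` for quick runs).
#' @return the run manifest (list), invisibly written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir = file.path(tempdir(), "wandertap-run"),
                         stages = c("simulate", "behavior", "probit"),
                         probit_args = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  cfg_hash <- config_hash(cfg_json)
  manifest_path <- file.path(out_dir, "manifest.json")
  old <- if (file.exists(manifest_path))
    jsonlite::fromJSON(manifest_path) else NULL
  reuse <- !is.null(old) && identical(old$config_hash, cfg_hash)
  manifest <- list(config_hash = cfg_hash, config = unclass(config),
                   artifacts = list(), reused = character(0),
                   warnings = character(0))

  session <- NULL
  need_session <- any(c("simulate", "behavior") %in% stages)
  if (need_session) session <- simulate_session(config)

  if ("simulate" %in% stages) {
    for (si in seq_len(config$n_subjects)) {
      f <- file.path(out_dir, sprintf("sub-%02d_events.tsv", si))
      if (reuse && file.exists(f)) {
        manifest$reused <- c(manifest$reused, basename(f))
      } else write_events_tsv(session$subjects[[si]], f)
      manifest$artifacts$events <- c(manifest$artifacts$events, basename(f))
    }
  }
  features <- NULL
  if ("behavior" %in% stages) {
    f <- file.path(out_dir, "probe_features.csv")
    if (reuse && file.exists(f)) {
      features <- utils::read.csv(f)
      manifest$reused <- c(manifest$reused, basename(f))
    } else {
      features <- probe_features(session)
      utils::write.csv(features, f, row.names = FALSE)
    }
    manifest$artifacts$features <- basename(f)
  }
  if ("probit" %in% stages) {
    if (is.null(features)) stop("probit stage requires the behavior stage")
    f <- file.path(out_dir, "model1_summary.csv")
    if (reuse && file.exists(f)) {
      manifest$reused <- c(manifest$reused, basename(f))
    } else {
      args <- utils::modifyList(list(features = features,
                                     seed = split_seed(config$seed, 11L)),
                                probit_args)
      rep1 <- do.call(run_model1, args)
      utils::write.csv(rep1$summary, f, row.names = FALSE)
      manifest$model1_r2 <- rep1$r2$mean
    }
    manifest$artifacts$model1 <- basename(f)
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

# order-sensitive polynomial rolling hash of the config JSON
config_hash <- function(json) {
  bytes <- utf8ToInt(as.character(json))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%d", as.integer(h))
}

#' Tabular report of a fitted probit model
#'
#' Mirrors the reporting style of the analysis: one row per coefficient
#' with posterior mean, 95% HDI, directional evidence ratio and
#' convergence diagnostics; optional atlas-overlap tables are appended
#' unchanged.
#'
#' @param model an `oprobit_report` (from [run_model1()] etc.).
#' @param overlap optional [atlas_overlap()] data.frame.
#' @return list of data.frames (`coefficients`, optionally `overlap`).
#' @export
report <- function(model, overlap = NULL) {
  stopifnot(inherits(model, "oprobit_report"))
  tab <- model$summary[seq_len(model$fit$p), ]
  out <- list(coefficients = tab)
  if (!is.null(overlap)) out$overlap <- overlap
  out
}
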