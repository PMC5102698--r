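## File interfaces: per-echo 4-d NIfTI volumes, BIDS-style events tables,
## and the simulator's ground-truth table.

#' Write a simulated subject to disk
#'
#' One 4-d NIfTI per echo (`sub-XX_echo-N_bold.nii.gz`), a BIDS-style
#' events table (`sub-XX_events.tsv`: onset, duration, trial_type), and a
#' truth table (`sub-XX_truth.tsv`: source, kind, amplitude, subject).
#'
#' @param subject an `me_subject` from [simulate_subject()].
#' @param dir output directory (created if needed).
#' @param sub subject label (zero-padded into the filenames).
#' @return invisibly, the vector of files written.
#' @export
write_me_subject <- function(subject, dir, sub = "01") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  series <- subject$series
  files <- character(0)
  for (e in seq_along(series$te_ms)) {
    f <- file.path(dir, sprintf("sub-%s_echo-%d_bold.nii.gz", sub, e))
    img <- RNifti::asNifti(series$echoes[[e]])
    RNifti::pixdim(img) <- c(rep(1, 3), series$tr_s)
    RNifti::writeNifti(img, f)
    files <- c(files, f)
  }
  fe <- file.path(dir, sprintf("sub-%s_events.tsv", sub))
  utils::write.table(subject$truth$design$events, fe, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  srcs <- subject$truth$sources
  tt <- data.frame(source = vapply(srcs, `[[`, "", "name"),
                   kind = vapply(srcs, `[[`, "", "kind"),
                   amplitude = vapply(srcs, `[[`, numeric(1), "amplitude"),
                   subject = rep(sub, length(srcs)),
                   stringsAsFactors = FALSE)
  ft <- file.path(dir, sprintf("sub-%s_truth.tsv", sub))
  utils::write.table(tt, ft, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(files, fe, ft))
}

#' Read per-echo NIfTI files into a multi-echo series
#'
#' @param files one NIfTI path per echo, ordered by echo time.
#' @param te_ms echo times, ms.
#' @param tr_s repetition time, s (taken from the first header's time
#'   pixdim when `NULL` and available).
#' @param mask optional logical mask array; when `NULL`, voxels whose
#'   first-echo temporal mean exceeds 10% of the maximum mean are used.
#' @return an [me_series()].
#' @export
read_me_series <- function(files, te_ms, tr_s = NULL, mask = NULL) {
  if (length(files) != length(te_ms))
    stop_invalid("one file per echo time required")
  echoes <- lapply(files, function(f) {
    arr <- as.array(RNifti::readNifti(f))
    if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr), 1)
    arr
  })
  if (is.null(tr_s)) {
    pd <- RNifti::pixdim(RNifti::readNifti(files[1]))
    tr_s <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  }
  if (is.null(mask)) {
    m <- rowMeans(vox_by_time(echoes[[1]]))
    mask <- array(m > 0.1 * max(m), dim(echoes[[1]])[1:3])
  }
  me_series(echoes, te_ms, tr_s, mask)
}

#' Read a BIDS-style events table
#'
#' @param path TSV with columns onset, duration, trial_type.
#' @param tr repetition time, s.
#' @param n_volumes run length in volumes.
#' @return a [task_design()].
#' @export
read_events <- function(path, tr, n_volumes) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  task_design(unique(ev$trial_type), ev, tr, n_volumes)
}

#' Write a 4-d time series as NIfTI
#'
#' @param ts a [timeseries4d()].
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  img <- RNifti::asNifti(ts$data)
  RNifti::pixdim(img) <- c(rep(1, 3), ts$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a six-column motion parameter table
#'
#' @param path whitespace-separated text, one row per volume, six columns.
#' @return numeric matrix (volumes x 6).
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6) stop_invalid("motion table must have six columns")
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Bundled cerebellar seed coordinates
#'
#' Right- and left-hemisphere cerebellar seed voxels (meta-analytic
#' mentalizing peaks) used for seed-based connectivity.
#'
#' @return data.frame with columns name, x, y, z.
#' @export
load_seed_table <- function() {
  utils::read.csv(system.file("extdata", "cerebellar_seeds.csv",
                              package = "echokit"),
                  stringsAsFactors = FALSE)
}
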