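#' Write a YC recording to a trace CSV with a JSON sidecar
#'
#' The CSV holds one row per frame and one column per ROI channel
#' (`yfp_roi001`, ..., `cfp_roi001`, ...) plus a `frame` column; session
#' layout, metadata and ground truth (when present) go to a JSON sidecar
#' next to it, never into the signal file.
#'
#' @param rec a `yc_recording`.
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return invisibly, the sidecar path.
#' @export
write_yc_recording <- function(rec, path) {
  stopifnot(inherits(rec, "yc_recording"))
  df <- data.frame(frame = seq_len(nrow(rec$yfp)))
  y <- as.data.frame(rec$yfp); names(y) <- paste0("yfp_", colnames(rec$yfp))
  c_ <- as.data.frame(rec$cfp); names(c_) <- paste0("cfp_", colnames(rec$cfp))
  utils::write.csv(cbind(df, y, c_), path, row.names = FALSE)
  side <- paste0(path, ".json")
  meta <- list(frame_interval = rec$frame_interval,
               applications = rec$applications,
               animal_id = rec$animal_id, slice_id = rec$slice_id,
               sex = rec$sex)
  if (!is.null(rec$truth)) {
    meta$truth <- list(responders = rec$truth$responders,
                       direction = rec$truth$direction,
                       depth = rec$truth$depth,
                       duration_fwhm = rec$truth$duration_fwhm)
  }
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a YC recording written by [write_yc_recording()]
#'
#' @param path CSV path with its `.json` sidecar alongside.
#' @return a `yc_recording` (without the noiseless ground-truth kernel,
#'   which is not serialized).
#' @export
read_yc_recording <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ycols <- grep("^yfp_", names(df), value = TRUE)
  ccols <- grep("^cfp_", names(df), value = TRUE)
  yfp <- as.matrix(df[ycols]); colnames(yfp) <- sub("^yfp_", "", ycols)
  cfp <- as.matrix(df[ccols]); colnames(cfp) <- sub("^cfp_", "", ccols)
  truth <- meta$truth
  if (!is.null(truth)) truth$responders <- as.matrix(truth$responders)
  structure(list(yfp = yfp, cfp = cfp,
                 frame_interval = meta$frame_interval,
                 applications = as.data.frame(meta$applications),
                 animal_id = meta$animal_id, slice_id = meta$slice_id,
                 sex = meta$sex, truth = truth),
            class = "yc_recording")
}

#' Write an immobility track to CSV plus a summary JSON
#'
#' @param track an `immobility_track`.
#' @param path frame-level CSV path (`frame`, `ts_wlt`, `immobile`); the
#'   epoch table goes to `paste0(path, ".epochs.csv")` and the summary to
#'   `paste0(path, ".json")`.
#' @return invisibly, the summary path.
#' @export
write_immobility_track <- function(track, path) {
  stopifnot(inherits(track, "immobility_track"))
  utils::write.csv(data.frame(frame = seq_along(track$ts_wlt),
                              ts_wlt = track$ts_wlt,
                              immobile = track$immobile),
                   path, row.names = FALSE)
  utils::write.csv(track$epochs, paste0(path, ".epochs.csv"),
                   row.names = FALSE)
  side <- paste0(path, ".json")
  jsonlite::write_json(list(sigma_wlt = track$sigma_wlt,
                            frame_rate = track$frame_rate,
                            total_immobility = track$total_immobility),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Write a hypnogram to CSV
#'
#' @param h a `hypnogram`.
#' @param path CSV path (`epoch`, `label`, `provenance`).
#' @return invisibly, `path`.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  utils::write.csv(data.frame(epoch = seq_along(h$labels),
                              label = h$labels,
                              provenance = h$provenance),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a hypnogram CSV (e.g. after manual rescoring)
#'
#' @param path CSV with `epoch`, `label` and optional `provenance`
#'   columns.
#' @param epoch_length seconds per epoch (default 4).
#' @return a `hypnogram`; epochs without a `provenance` entry are marked
#'   `"manual"` (imported labels are assumed curated).
#' @export
read_hypnogram <- function(path, epoch_length = 4) {
  df <- utils::read.csv(path)
  bad <- setdiff(unique(df$label), c("W", "NR", "R"))
  if (length(bad)) stop("unknown state label(s): ", paste(bad, collapse = ", "))
  structure(list(labels = as.character(df$label),
                 epoch_length = epoch_length,
                 provenance = if ("provenance" %in% names(df))
                   as.character(df$provenance)
                 else rep("manual", nrow(df)),
                 thresholds = NULL),
            class = "hypnogram")
}
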