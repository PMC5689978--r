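# RT Plan I/O for HDR brachytherapy plans.
#
# Channel encoding (the one dialect this package reads and writes):
# each catheter is one item of the Channel Sequence. Its Brachy Control Point
# Sequence first lists the catheter path control points tip-first, each with
# an unchanged cumulative time weight, followed by one *pair* of control
# points per dwell (both at the dwell position, weights w_before and w_after).
# Dwell times are reconstructed with the standard RT Plan rule
#   t_i = (w_after - w_before) / FinalCumulativeTimeWeight * ChannelTotalTime
# where cumulative weights are written in seconds, so the final weight equals
# the channel total time. A weight increase between control points at
# different positions does not occur in this dialect and is flagged as an
# unknown layout.

#' Write a brachytherapy plan as a DICOM RT Plan file
#'
#' @param plan A [plan_model()].
#' @param path Output file path.
#' @param seed Integer seed for the deterministic UID stream.
#' @return `path`, invisibly.
#' @export
write_rtplan <- function(plan, path, seed = 1L) {
  validate_plan_model(plan)
  uid <- dcm_uid_factory(seed)
  study <- uid(); series <- uid(); sop <- uid()

  channels <- lapply(plan$catheters, function(ca) {
    dw <- plan$dwells[plan$dwells$catheter_id == ca$id, , drop = FALSE]
    total <- sum(dw$time)
    cps <- list()
    idx <- 0L
    add_cp <- function(pos, weight) {
      cps[[length(cps) + 1L]] <<- list(
        dcm_el(0x300a, 0x0112, "IS", idx),
        dcm_el(0x300a, 0x02d4, "DS", pos),
        dcm_el(0x300a, 0x02d6, "DS", weight))
      idx <<- idx + 1L
    }
    for (i in seq_len(nrow(ca$control_points)))
      add_cp(ca$control_points[i, ], 0)
    w <- 0
    for (i in seq_len(nrow(dw))) {
      pos <- as.numeric(dw[i, c("x", "y", "z")])
      add_cp(pos, w)
      w <- w + dw$time[i]
      add_cp(pos, w)
    }
    list(
      dcm_el(0x300a, 0x0110, "IS", idx),
      dcm_el(0x300a, 0x0282, "IS", ca$id),
      dcm_el(0x300a, 0x0286, "DS", total),
      dcm_el(0x300a, 0x0288, "CS", "STEPWISE"),
      dcm_el(0x300a, 0x02c8, "DS", total),
      dcm_el(0x300a, 0x02d0, "SQ", cps)
    )
  })

  els <- list(
    dcm_el(0x0008, 0x0016, "UI", SOP_CLASS[["rtplan"]]),
    dcm_el(0x0008, 0x0018, "UI", sop),
    dcm_el(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_el(0x0020, 0x000d, "UI", study),
    dcm_el(0x0020, 0x000e, "UI", series),
    dcm_el(0x300a, 0x0002, "SH", "brachydeck"),
    dcm_el(0x300a, 0x0010, "SQ", list(list(
      dcm_el(0x300a, 0x0012, "IS", 1L),
      dcm_el(0x300a, 0x0026, "DS",
             if (is.na(plan$prescription_dose)) 0 else plan$prescription_dose)
    ))),
    dcm_el(0x300a, 0x0210, "SQ", list(list(
      dcm_el(0x300a, 0x0212, "IS", 1L),
      dcm_el(0x300a, 0x0214, "CS", "CYLINDER"),
      dcm_el(0x300a, 0x0226, "LO", plan$source_id)
    ))),
    dcm_el(0x300a, 0x0230, "SQ", list(list(
      dcm_el(0x300a, 0x0234, "IS", 1L),
      dcm_el(0x300a, 0x0280, "SQ", channels)
    )))
  )
  dcm_write_file(path, els, SOP_CLASS[["rtplan"]], sop)
}

#' Read a DICOM RT Plan file into a plan model
#'
#' Dwell positions are returned in mm with cumulative time weights converted
#' to per-dwell times in seconds; catheter control points are parsed from the
#' channel geometry. Plans with missing dwell weights or zero total time are
#' rejected.
#'
#' @param path RT Plan file path.
#' @return A [plan_model()].
#' @export
read_rtplan <- function(path) {
  ds <- dcm_read_file(path)
  if (!identical(dcm_get(ds, 0x0008, 0x0060), "RTPLAN"))
    stop("not an RT Plan file: ", path)
  presc <- NA_real_
  dref <- dcm_get(ds, 0x300a, 0x0010)
  if (!is.null(dref) && length(dref) > 0) {
    p <- dcm_get(dref[[1]], 0x300a, 0x0026)
    if (!is.null(p) && p > 0) presc <- p
  }
  source_id <- "unknown"
  ssq <- dcm_get(ds, 0x300a, 0x0210)
  if (!is.null(ssq) && length(ssq) > 0) {
    sid <- dcm_get(ssq[[1]], 0x300a, 0x0226)
    if (!is.null(sid)) source_id <- sid
  }
  asq <- dcm_req(ds, 0x300a, 0x0230, "ApplicationSetupSequence")
  if (length(asq) < 1L) stop("RT Plan has no application setup")
  chans <- dcm_req(asq[[1]], 0x300a, 0x0280, "ChannelSequence")
  if (length(chans) < 1L) stop("RT Plan has no channels")

  catheters <- list()
  dwl <- list()
  for (ch in chans) {
    cid <- as.integer(dcm_req(ch, 0x300a, 0x0282, "ChannelNumber"))
    total <- dcm_req(ch, 0x300a, 0x0286, "ChannelTotalTime")
    final_w <- dcm_req(ch, 0x300a, 0x02c8, "FinalCumulativeTimeWeight")
    cps <- dcm_req(ch, 0x300a, 0x02d0, "BrachyControlPointSequence")
    pos <- t(vapply(cps, function(cp)
      dcm_req(cp, 0x300a, 0x02d4, "ControlPoint3DPosition"), numeric(3)))
    w <- vapply(cps, function(cp) {
      v <- dcm_get(cp, 0x300a, 0x02d6)
      if (is.null(v)) NA_real_ else v
    }, numeric(1))
    if (anyNA(w))
      stop("missing dwell (cumulative time) weights in channel ", cid)
    path_pts <- list()
    i <- 1L
    n <- nrow(pos)
    while (i <= n) {
      if (i < n && all(abs(pos[i, ] - pos[i + 1L, ]) < 1e-9) &&
          w[i + 1L] > w[i]) {
        # dwell pair: t = dw / final_w * total
        t_i <- (w[i + 1L] - w[i]) / final_w * total
        dwl[[length(dwl) + 1L]] <- data.frame(
          catheter_id = cid, x = pos[i, 1], y = pos[i, 2], z = pos[i, 3],
          time = t_i)
        i <- i + 2L
      } else {
        if (i < n && w[i + 1L] > w[i])
          stop("unknown channel control-point layout in channel ", cid,
               ": time weight increases between distinct positions")
        path_pts[[length(path_pts) + 1L]] <- pos[i, ]
        i <- i + 1L
      }
    }
    if (length(path_pts) < 2L)
      stop("channel ", cid, " has fewer than 2 path control points")
    catheters[[length(catheters) + 1L]] <- list(
      id = cid, control_points = do.call(rbind, path_pts))
  }
  if (length(dwl) == 0L) stop("RT Plan contains no dwells")
  dwells <- do.call(rbind, dwl)
  dwells$index <- seq_len(nrow(dwells))
  if (sum(dwells$time) <= 0) stop("RT Plan has zero total time")
  plan_model(source_id, catheters, dwells, presc)
}
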