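#' Inspect one cycle of frames end to end
#'
#' The complete desk-scale workflow for one nest visit: each frame goes
#' through the detection provider (failures count as "no" votes), the
#' per-frame detections are fused by T-of-N majority voting into an egg
#' count, the cage label is decoded from the first frame that yields a
#' valid barcode, and the resulting position-quantity pair is appended to
#' the record store.
#'
#' @param frames list of N RGB frames (H x W x 3, 0-255).
#' @param store optional [record_store()]; when `NULL` no record is
#'   written.
#' @param detector_cfg a [detector_config()].
#' @param policy a [voting_policy()] (its N must equal `length(frames)`).
#' @param provider detection provider; defaults to the classical reference
#'   detector with `detector_cfg`.
#' @param prefix EAN-13 embedding prefix.
#' @param time timestamp for the record.
#' @param ... further arguments passed to [read_cage_label()].
#' @return list with `uid`, `number` (fused count), `decision` (the
#'   [fuse_count()] result), `code` (13-digit barcode), and `record` (the
#'   appended row, or `NULL` when no store was given). When every frame
#'   fails barcode decoding a positioning error is raised and nothing is
#'   recorded.
#' @export
inspect_cycle <- function(frames, store = NULL,
                          detector_cfg = detector_config(),
                          policy = voting_policy(),
                          provider = NULL, prefix = "2000",
                          time = Sys.time(), ...) {
  if (is.null(provider)) {
    provider <- function(img) detect_eggs(img, detector_cfg)
  }
  results <- run_provider(frames, provider)
  decision <- fuse_count(results, policy)
  label <- NULL
  for (img in frames) {
    label <- tryCatch(read_cage_label(img, prefix = prefix, ...),
                      error = function(e) NULL)
    if (!is.null(label)) break
  }
  if (is.null(label)) {
    no_barcode_error(
      "positioning failed: no frame yielded a decodable cage barcode")
  }
  record <- NULL
  if (!is.null(store)) {
    record <- add_record(store, label$uid, decision$fused_count, time)
  }
  list(uid = label$uid, number = decision$fused_count,
       decision = decision, code = label$code, record = record)
}

#' Render and inspect one synthetic cycle
#'
#' Fixture helper binding the generator to the full chain: renders the
#' cycle, runs [inspect_cycle()], and reports the result alongside the
#' ground truth.
#'
#' @param cspec a [cycle_spec()].
#' @inheritParams inspect_cycle
#' @return the [inspect_cycle()] result plus `truth` (the generator's
#'   ground truth).
#' @export
run_cycle_fixture <- function(cspec, store = NULL,
                              detector_cfg = detector_config(),
                              policy = voting_policy(), ...) {
  rc <- render_cycle(cspec)
  out <- inspect_cycle(rc$frames, store = store, detector_cfg = detector_cfg,
                       policy = policy, ...)
  out$truth <- rc$truth
  out$occluded <- rc$occluded
  out
}
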