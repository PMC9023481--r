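#' Run the complete P wave detection pipeline
#'
#' Executes the eight stages in order: (a) QRS detection on the cleaned,
#' band-passed, phasor-transformed signal with adaptive threshold and backward
#' search; (b) T wave localization; (c) PVC flagging by QRS area; (d) AFIB
#' flagging by symbolic dynamics and Shannon entropy; (e) the per-beat
#' pathology gate; (f) conducted P search; (g) dissociated P search in long
#' pauses; (h) two-criterion verification of every candidate. Identical input
#' and config give bit-identical output.
#'
#' @param rec an [ecg_record()], at least 2 s long
#' @param cfg a [detector_config()]
#' @param verbose emit a per-beat decision trace with `message()`
#' @return a list of class `pwave_result`:
#' \describe{
#'   \item{beats}{a `beat_set` with per-beat flags, T positions and accepted
#'     conducted P positions}
#'   \item{candidates}{data frame of every P candidate (normal and
#'     dissociated) with `accepted` and `rejection_reason`; skipped beats are
#'     recorded with reason `afib_skip`/`pvc_skip`, failed gates with
#'     `no_dissociation` absent (the gate simply does not open)}
#'   \item{p_accepted}{sorted sample indices of all accepted P waves
#'     (conducted and dissociated)}
#'   \item{annotations}{a [wave_annotations()] with detected P, T and R}
#' }
#' @export
run_pipeline <- function(rec, cfg = detector_config(), verbose = FALSE) {
  assert_detectable(rec)
  fs <- rec$fs
  say <- function(...) if (verbose) message(sprintf(...))

  # (a) preprocessing + QRS
  xl <- highpass_lynn(rec, cfg$lynn_fc)
  xc <- clean_ecg(rec, cfg)
  bp <- bandpass_qrs(ecg_record(xc$samples, fs, rec$lead, rec$record_id),
                     cfg$qrs_band)
  beats <- detect_qrs(bp, cfg)
  nb <- length(beats$r_peaks)
  say("QRS: %d beats", nb)
  if (nb == 0) {
    empty <- wave_annotations(source = "detected")
    return(structure(list(beats = beats,
                          candidates = p_candidate(integer(0), integer(0),
                                                   numeric(0), character(0))[0, ],
                          p_accepted = integer(0), annotations = empty,
                          record_id = rec$record_id, fs = fs),
                     class = "pwave_result"))
  }

  # (b) T waves
  beats <- detect_t(xc, beats, cfg)

  # (c) PVC
  auc <- compute_auc(xl, beats, cfg)
  beats$pvc <- detect_pvc(auc, cfg)

  # (d) AFIB
  ent <- symbolic_entropy(beats, cfg)
  beats$afib <- detect_afib(ent, beats$pvc, cfg)
  say("flags: %d PVC, %d AFIB", sum(beats$pvc), sum(beats$afib))

  # (e)-(h) per-beat decisions
  cands <- list()
  diss_in_prev <- FALSE
  for (i in seq_len(nb)) {
    gate <- pathology_check(beats, i)
    t_prev <- if (i >= 2) beats$t_peaks[i - 1] else NA_integer_
    if (gate != "proceed") {
      reason <- if (gate == "skip_afib") "afib_skip" else "pvc_skip"
      cands[[length(cands) + 1]] <-
        p_candidate(i, NA_integer_, NA_real_, "normal", FALSE, reason)
      say("beat %d: %s", i, reason)
      diss_in_prev <- FALSE
      next
    }

    # (f) conducted P + (h) verification
    u_qrs <- xc$samples[beats$r_peaks[i]]
    cand <- detect_normal_p(xc, beats, i, cfg)
    cand <- verify_p(cand, u_qrs, t_prev, cfg)
    p_ref <- NA_integer_
    if (!is.null(cand)) {
      cands[[length(cands) + 1]] <- cand
      if (cand$accepted) {
        beats$p_peaks[i] <- cand$position
        p_ref <- cand$position
      }
      say("beat %d: normal P %s at %d", i,
          if (cand$accepted) "accepted" else cand$rejection_reason,
          cand$position)
    }
    if (is.na(p_ref)) {
      w <- p_search_window(beats$r_peaks[i], beats$rr[i], fs, cfg,
                           sig_len = length(xc$samples))
      if (!is.null(w)) p_ref <- w[1]
    }

    # (g) dissociated P + (h) verification
    diss_here <- FALSE
    if (i >= 3 &&
        dissociation_gate(beats$rr[i], beats$rr[i - 1], beats$pvc[i],
                          diss_in_prev, cfg)) {
      dcand <- detect_dissociated_p(xc, t_prev, p_ref, i, cfg)
      dcand <- verify_p(dcand, u_qrs, t_prev, cfg)
      if (!is.null(dcand)) {
        cands[[length(cands) + 1]] <- dcand
        diss_here <- dcand$accepted
        say("beat %d: dissociated P %s at %d", i,
            if (dcand$accepted) "accepted" else dcand$rejection_reason,
            dcand$position)
      }
    }
    diss_in_prev <- diss_here
  }

  candidates <- if (length(cands)) do.call(rbind, cands) else
    p_candidate(integer(0), integer(0), numeric(0), character(0))[0, ]
  acc <- candidates[candidates$accepted & !is.na(candidates$position), ]
  p_acc <- sort(unique(acc$position))
  ann <- wave_annotations(
    p_peaks = p_acc,
    t_peaks = sort(unique(beats$t_peaks[!is.na(beats$t_peaks)])),
    r_peaks = beats$r_peaks,
    source = "detected", sig_len = length(rec$samples)
  )
  structure(list(beats = beats, candidates = candidates, p_accepted = p_acc,
                 annotations = ann, record_id = rec$record_id, fs = fs),
            class = "pwave_result")
}

#' @export
print.pwave_result <- function(x, ...) {
  cat(sprintf("<pwave_result> %s: %d beats, %d accepted P (%d PVC, %d AFIB beats)\n",
              x$record_id, length(x$beats$r_peaks), length(x$p_accepted),
              sum(x$beats$pvc), sum(x$beats$afib)))
  invisible(x)
}
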