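# Protein architecture summaries, canonical transcript selection, and
# presence calls with the calibrated score thresholds.

#' Default presence-call thresholds
#'
#' The calibrated decision boundaries: aKRAB against six-frame genome
#' translations is present at scores >= 30; aKRAB against annotated
#' proteins is absent at <= 20, present at >= 50 and uncertain between
#' (the 38-45 score region is kept distinct from the >50 region); ePR-SET
#' is present at >= 180 (scores from true orthologues sit above the
#' 180-250 gap).
#'
#' @return nested list of thresholds, editable and passable to
#'   [call_presence()].
#' @export
presence_thresholds <- function() {
  list(
    akrab = list(genome_present = 30, protein_absent = 20,
                 protein_present = 50),
    eprset = list(present = 180)
  )
}

#' Call domain presence from a best score
#'
#' @param best_score the best window score for the model on one sequence
#'   set (one species, one protein, or one genome).
#' @param model `"akrab"` or `"eprset"`.
#' @param context `"protein"` for annotated-protein scans, `"genome"` for
#'   six-frame translation scans (the genome scan uses a single
#'   absence/presence boundary; the protein scan has an uncertain band).
#' @param thresholds threshold set, see [presence_thresholds()].
#' @return list of class `presence_call`: `model`, `context`,
#'   `best_score`, `call` in `present`/`absent`/`uncertain`, `thresholds`.
#' @export
call_presence <- function(best_score, model = c("akrab", "eprset"),
                          context = c("protein", "genome"),
                          thresholds = presence_thresholds()) {
  model <- match.arg(model)
  context <- match.arg(context)
  stopifnot(is.finite(best_score))
  th <- thresholds[[model]]
  if (is.null(th)) stop("unknown model name: ", model)
  call <- if (model == "akrab") {
    if (context == "genome") {
      if (best_score >= th$genome_present) "present" else "absent"
    } else {
      if (best_score <= th$protein_absent) "absent"
      else if (best_score >= th$protein_present) "present"
      else "uncertain"
    }
  } else {
    if (best_score >= th$present) "present" else "absent"
  }
  structure(list(model = model, context = context, best_score = best_score,
                 call = call, thresholds = th),
            class = "presence_call")
}

#' @export
print.presence_call <- function(x, ...) {
  cat(sprintf("%s (%s scan): score %.2f -> %s\n",
              x$model, x$context, x$best_score, x$call))
  invisible(x)
}

#' Summarise one protein's domain architecture
#'
#' Scans the protein with the given profile models and the zinc-finger
#' detector and assembles the ordered architecture summary.
#'
#' @param seq protein sequence.
#' @param profiles named list of [build_profile()] models; names should
#'   include `akrab` and/or `prset`-like models.
#' @param protein_id identifier.
#' @param thresholds per-model score thresholds for reported hits (named
#'   numeric; defaults to 0 for unlisted models).
#' @param array_gap passed to [detect_zn_fingers()].
#' @return list of class `protein_architecture`: `protein_id`, `hits`
#'   (data.frame, all models, ordered by start), `has_akrab`,
#'   `prset_present`, `n_zn_fingers`, `zn_arrays`, `best_scores` (named).
#' @export
protein_architecture <- function(seq, profiles, protein_id = "protein",
                                 thresholds = NULL, array_gap = 15) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  hits <- list()
  best <- stats::setNames(numeric(length(profiles)), names(profiles))
  for (nm in names(profiles)) {
    thr <- if (!is.null(thresholds) && nm %in% names(thresholds))
      thresholds[[nm]] else 0
    h <- scan_peptides(profiles[[nm]], seq, seq_id = protein_id,
                       threshold = thr)
    best[nm] <- if (nrow(h)) max(h$score) else -Inf
    hits[[nm]] <- h[h$above_threshold, , drop = FALSE]
  }
  hits <- do.call(rbind, hits)
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  zn <- detect_zn_fingers(seq, array_gap = array_gap)
  structure(list(protein_id = protein_id, hits = hits,
                 has_akrab = "akrab" %in% hits$model,
                 prset_present = any(grepl("prset", hits$model)),
                 n_zn_fingers = nrow(zn$fingers),
                 zn_arrays = zn$arrays, best_scores = best),
            class = "protein_architecture")
}

#' @export
print.protein_architecture <- function(x, ...) {
  cat(sprintf("%s: aKRAB=%s, PR-SET=%s, %d Zn fingers in %d array(s)\n",
              x$protein_id, x$has_akrab, x$prset_present,
              x$n_zn_fingers, nrow(x$zn_arrays)))
  invisible(x)
}

#' Select the canonical transcript of a gene
#'
#' Among a gene's transcripts, the canonical one carries the largest number
#' of distinct domain models; ties are broken by the largest summed hit
#' length, and remaining ties by the lexicographically smallest transcript
#' id.
#'
#' @param architectures named list: transcript id -> data.frame of hits
#'   with columns `model`, `start`, `end` (e.g. the `hits` element of
#'   [protein_architecture()]).
#' @return the canonical transcript id.
#' @export
select_canonical <- function(architectures) {
  stopifnot(is.list(architectures), length(architectures) >= 1L,
            !is.null(names(architectures)))
  ids <- names(architectures)
  n_models <- vapply(architectures, function(h)
    length(unique(h$model)), integer(1))
  tot_len <- vapply(architectures, function(h)
    if (nrow(h)) sum(h$end - h$start + 1L) else 0L, numeric(1))
  ord <- order(-n_models, -tot_len, ids)
  ids[ord[1]]
}
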