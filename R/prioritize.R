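#' Consensus score over functional predictors and conservation
#'
#' Counts damaging votes among the four predictors (SIFT `DAMAGING`,
#' MutationTaster `disease_causing`, PolyPhen-2 `damaging`, PMut
#' `pathological`), relative to the number of non-missing calls, and
#' flags evolutionary conservation at `gerp >= gerp_conserved_threshold`.
#' The score is `damaging_votes / votes_available` plus a conservation
#' bonus of `conservation_weight` when conserved.  The score is
#' undefined (NA, flagged) when every predictor is missing; such
#' variants rank last.  Flipping any single predictor from benign to
#' damaging can never lower the score.
#'
#' @param sift,mutation_taster,polyphen2,pmut character vectors of
#'   predictor calls in their closed vocabularies (`NA` = missing);
#'   see [normalize_predictor_call()]
#' @param gerp numeric GERP conservation scores (`NA` = missing)
#' @param gerp_conserved_threshold GERP at or above which a site counts
#'   as conserved (default 4.0, an artifact choice, configurable)
#' @param conservation_weight additive bonus for conserved sites
#'   (default 0.25)
#' @return data.frame with `damaging_votes`, `votes_available`,
#'   `conserved`, `score`, `score_defined`
#' @export
consensus_score <- function(sift = NA, mutation_taster = NA,
                            polyphen2 = NA, pmut = NA, gerp = NA,
                            gerp_conserved_threshold = 4.0,
                            conservation_weight = 0.25) {
  n <- max(length(sift), length(mutation_taster), length(polyphen2),
           length(pmut), length(gerp))
  sift <- rep_len(as.character(sift), n)
  mutation_taster <- rep_len(as.character(mutation_taster), n)
  polyphen2 <- rep_len(as.character(polyphen2), n)
  pmut <- rep_len(as.character(pmut), n)
  gerp <- rep_len(as.numeric(gerp), n)
  chk <- function(x, col) normalize_predictor_call(x, col)
  calls <- cbind(chk(sift, "sift") == "DAMAGING",
                 chk(mutation_taster, "mutation_taster") == "disease_causing",
                 chk(polyphen2, "polyphen2") == "damaging",
                 chk(pmut, "pmut") == "pathological")
  votes <- rowSums(calls, na.rm = TRUE)
  avail <- rowSums(!is.na(calls))
  conserved <- !is.na(gerp) & gerp >= gerp_conserved_threshold
  score <- ifelse(avail > 0,
                  votes / pmax(avail, 1) + conservation_weight * conserved,
                  NA_real_)
  data.frame(damaging_votes = votes, votes_available = avail,
             conserved = conserved, score = score,
             score_defined = avail > 0)
}

#' Rank candidate variants
#'
#' Total, deterministic order: candidates absent from the healthy
#' control panel come first; ties break by consensus score (descending,
#' undefined scores last), then GERP (descending, missing last), then
#' gene symbol (lexicographic).  Input order never affects the result.
#'
#' @param candidates data.frame with at least `gene`; optional `id`,
#'   `gerp`
#' @param scores data.frame from [consensus_score()], row-aligned with
#'   `candidates`
#' @param control_carriers non-negative integer vector: carriers of each
#'   candidate among the screened healthy controls
#' @param evs_inhouse_occurrence optional non-negative occurrence counts
#'   in EVS/in-house resources, used as a final pre-gene tiebreak
#'   (ascending)
#' @return the candidates data.frame, ordered, with appended score
#'   columns, `control_carriers` and `rank`
#' @export
rank_candidates <- function(candidates, scores, control_carriers,
                            evs_inhouse_occurrence = NULL) {
  stopifnot(nrow(candidates) == nrow(scores),
            length(control_carriers) == nrow(candidates),
            all(control_carriers >= 0))
  if (is.null(evs_inhouse_occurrence))
    evs_inhouse_occurrence <- rep(0, nrow(candidates))
  out <- cbind(candidates, scores,
               control_carriers = control_carriers,
               evs_inhouse_occurrence = evs_inhouse_occurrence)
  score_key <- ifelse(is.na(out$score), -Inf, out$score)
  gerp_key <- if (is.null(out$gerp)) rep(0, nrow(out)) else
    ifelse(is.na(out$gerp), -Inf, out$gerp)
  ord <- order(out$control_carriers > 0,      # absent-from-panel first
               -score_key, -gerp_key,
               evs_inhouse_occurrence, out$gene, method = "radix")
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
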