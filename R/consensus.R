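# Expert-vote aggregation: strict-majority scoring, the DBA
# (difference-between-answers) statistic, its confidence bands,
# outlier-expert removal, repository filtering and lateral->dorsal score
# transfer.
#
# DBA = max(votes) - (sum(votes) - max(votes)) = 2*max - sum.  The bands
# are taken literally from the published if-then table; note they behave
# oddly on unanimous panels (e.g. votes [2,2,2] give DBA = -2, the 0%
# band), which is surfaced in the documentation rather than corrected.

#' Expert x video vote table
#'
#' Validates and classes a long-format table of ordinal locomotion votes.
#'
#' @param entries A data.frame with columns `video_id`, `expert_id`,
#'   `score` (integers 0-3), at most one row per (video, expert).
#' @return The validated data.frame with class `vote_table`.
#' @export
vote_table <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("video_id", "expert_id", "score")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop_validation("vote table missing column(s): %s",
                    paste(miss, collapse = ", "))
  if (nrow(entries) == 0L) stop_validation("vote table is empty")
  if (!all(entries$score %in% 0:3))
    stop_validation("scores must be integers in 0..3")
  key <- paste(entries$video_id, entries$expert_id, sep = "\r")
  if (anyDuplicated(key))
    stop_validation("duplicate vote for (video, expert): %s",
                    sub("\r", ", ", key[duplicated(key)][1L]))
  entries$score <- as.integer(entries$score)
  class(entries) <- c("vote_table", "data.frame")
  entries
}

#' Strict-majority consensus score
#'
#' Returns the score indicated by strictly more than 50% of the votes, or
#' `NA` ("unresolved") when no score reaches a strict majority (exact 50%
#' ties are unresolved).
#'
#' @param votes Nonempty integer vector of scores 0-3.
#' @return Integer score, or `NA_integer_` if unresolved.
#' @export
majority_score <- function(votes) {
  if (length(votes) == 0L) stop_validation("empty vote list")
  if (!all(votes %in% 0:3)) stop_validation("votes must be integers in 0..3")
  tab <- table(votes)
  top <- which.max(tab)
  if (tab[top] * 2L > length(votes)) as.integer(names(tab)[top])
  else NA_integer_
}

#' Difference between answers (DBA)
#'
#' `DBA = max(v) - (sum(v) - max(v)) = 2*max(v) - sum(v)`, evaluated
#' literally (no clamping).  `v` is the raw vote vector (`mode = "raw"`,
#' default) or the set of distinct answered scores (`mode = "distinct"`);
#' both readings of the published formula are defensible, see the methods
#' vignette.
#'
#' @param votes Nonempty integer vector of scores 0-3.
#' @param mode `"raw"` or `"distinct"`.
#' @return Numeric DBA value.
#' @export
compute_dba <- function(votes, mode = c("raw", "distinct")) {
  mode <- match.arg(mode)
  if (length(votes) == 0L) stop_validation("empty vote list")
  if (!all(votes %in% 0:3)) stop_validation("votes must be integers in 0..3")
  v <- if (mode == "distinct") unique(votes) else votes
  2 * max(v) - sum(v)
}

.band_levels <- c("0%", "25%", "75%", "100%", "out_of_range")

#' Map a DBA value to its confidence band
#'
#' Ordered half-open bands: `dba < -1` gives 0%, `[-1, 0)` gives 25%,
#' `[0, 1)` gives 75%, `[1, 2)` gives 100%.  `dba >= 2` falls outside the
#' published table; the default policy labels it `"out_of_range"`, the
#' `"clamp"` policy maps it to 100%.
#'
#' @param dba Numeric vector of DBA values.
#' @param policy `"out_of_range"` (default) or `"clamp"`.
#' @return Character vector of band labels (`"0%"`, `"25%"`, `"75%"`,
#'   `"100%"`, `"out_of_range"`).
#' @export
confidence_from_dba <- function(dba, policy = c("out_of_range", "clamp")) {
  policy <- match.arg(policy)
  if (!is.numeric(dba) || anyNA(dba))
    stop_validation("`dba` must be numeric without NAs")
  out <- character(length(dba))
  out[dba < -1] <- "0%"
  out[dba >= -1 & dba < 0] <- "25%"
  out[dba >= 0 & dba < 1] <- "75%"
  out[dba >= 1 & dba < 2] <- "100%"
  out[dba >= 2] <- if (policy == "clamp") "100%" else "out_of_range"
  out
}

#' Numeric value of a confidence band label
#' @param band Character vector of band labels.
#' @return Numeric percentages (NA for `"out_of_range"`).
#' @export
confidence_percent <- function(band) {
  map <- c("0%" = 0, "25%" = 25, "75%" = 75, "100%" = 100,
           out_of_range = NA_real_)
  unknown <- setdiff(band, names(map))
  if (length(unknown))
    stop_validation("unknown band label: %s", paste(unknown, collapse = ", "))
  unname(map[band])
}

#' Flag outlier experts
#'
#' Concretization of the published "box plot" screening: each expert's
#' deviation is the mean absolute difference between their votes and the
#' panel median for the same video; experts whose deviation exceeds
#' `Q3 + fence * IQR` of the deviation distribution (Tukey fence, type-7
#' quantiles) are flagged.
#'
#' @param table A [vote_table()] with at least 4 experts.
#' @param fence Tukey fence multiplier (default 1.5).
#' @return Character vector of flagged expert ids (possibly empty), with
#'   the per-expert deviations attached as attribute `"deviation"`.
#' @export
detect_outlier_experts <- function(table, fence = 1.5) {
  table <- vote_table(table)
  if (!is.numeric(fence) || length(fence) != 1L || is.na(fence) || fence < 0)
    stop_validation("`fence` must be a nonnegative number (Inf allowed)")
  experts <- unique(table$expert_id)
  if (length(experts) < 4L)
    stop_validation("need at least 4 experts (got %d)", length(experts))
  med <- tapply(table$score, table$video_id, stats::median)
  dev_per_vote <- abs(table$score - med[table$video_id])
  dev <- tapply(dev_per_vote, table$expert_id, mean)[experts]
  q <- stats::quantile(dev, c(0.25, 0.75), names = FALSE, type = 7)
  cut <- if (is.finite(fence)) q[2L] + fence * (q[2L] - q[1L]) else Inf
  flagged <- experts[dev > cut]
  attr(flagged, "deviation") <- dev
  attr(flagged, "cutoff") <- cut
  flagged
}

#' Per-video consensus results
#'
#' Applies [majority_score()], [compute_dba()] and [confidence_from_dba()]
#' to every video in a vote table.
#'
#' @param table A [vote_table()].
#' @param dba_mode Passed to [compute_dba()].
#' @param policy Passed to [confidence_from_dba()].
#' @return data.frame with columns `video_id`, `final_score` (NA when
#'   unresolved), `dba`, `band`.
#' @export
consensus_results <- function(table, dba_mode = "raw",
                              policy = "out_of_range") {
  table <- vote_table(table)
  ids <- unique(table$video_id)
  res <- lapply(ids, function(v) {
    votes <- table$score[table$video_id == v]
    dba <- compute_dba(votes, mode = dba_mode)
    data.frame(video_id = v, final_score = majority_score(votes),
               dba = dba, band = confidence_from_dba(dba, policy = policy),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Build the scored video repository
#'
#' Assigns each manifest video its majority score, DBA and confidence
#' band, then retains only videos with a resolved score and a band of 75%
#' or 100%.  The result mirrors the published repository accounting: a
#' per-video table, per-(score x band) counts, and exclusion percentages.
#'
#' @param table A [vote_table()].
#' @param manifest data.frame with a `video_id` column (unique ids); an
#'   optional logical `unassessed` column marks videos without votes.
#' @param dba_mode,policy Passed to [consensus_results()].
#' @return List of class `sow_repository`: `videos` (per-video table with
#'   `included` flag), `counts` (score x band table over included videos),
#'   `n_total`, `n_included`, `n_excluded`, `exclusion_pct`.
#' @export
build_repository <- function(table, manifest, dba_mode = "raw",
                             policy = "out_of_range") {
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  if (!"video_id" %in% names(manifest))
    stop_validation("manifest must have a `video_id` column")
  if (anyDuplicated(manifest$video_id))
    stop_validation("duplicate video id in manifest: %s",
                    manifest$video_id[duplicated(manifest$video_id)][1L])
  unassessed <- if ("unassessed" %in% names(manifest))
    as.logical(manifest$unassessed) else rep(FALSE, nrow(manifest))
  res <- consensus_results(table, dba_mode = dba_mode, policy = policy)
  novotes <- setdiff(manifest$video_id[!unassessed], res$video_id)
  if (length(novotes))
    stop_validation("manifest video(s) without votes and not marked unassessed: %s",
                    paste(utils::head(novotes, 3), collapse = ", "))
  idx <- match(manifest$video_id, res$video_id)
  videos <- data.frame(
    video_id = manifest$video_id,
    final_score = res$final_score[idx],
    dba = res$dba[idx],
    band = res$band[idx],
    stringsAsFactors = FALSE
  )
  videos$included <- !is.na(videos$final_score) &
    !is.na(videos$band) & videos$band %in% c("75%", "100%")
  inc <- videos[videos$included, , drop = FALSE]
  counts <- base::table(score = factor(inc$final_score, levels = 0:3),
                        band = factor(inc$band, levels = c("75%", "100%")))
  n_total <- nrow(videos)
  n_included <- nrow(inc)
  structure(
    list(videos = videos, counts = counts,
         n_total = n_total, n_included = n_included,
         n_excluded = n_total - n_included,
         exclusion_pct = 100 * (n_total - n_included) / n_total),
    class = "sow_repository"
  )
}

#' @export
print.sow_repository <- function(x, ...) {
  cat(sprintf("<sow_repository> %d videos: %d retained, %d excluded (%.2f%%)\n",
              x$n_total, x$n_included, x$n_excluded, x$exclusion_pct))
  print(x$counts)
  invisible(x)
}

#' Transfer lateral consensus scores to paired dorsal videos
#'
#' Only the lateral view was scored by the expert panel; the score, DBA and
#' band of each lateral video are copied verbatim to its paired dorsal
#' video.  Lateral videos without a pairing are dropped with a warning.
#'
#' @param lateral data.frame of resolved consensus results (columns
#'   `video_id`, `final_score`, `dba`, `band`).
#' @param pairing Named character vector mapping lateral video ids to
#'   dorsal video ids (injective, no NAs).
#' @param dorsal_ids Optional vector of valid dorsal ids; pairings to ids
#'   outside it raise an error.
#' @return data.frame of dorsal consensus results.
#' @export
transfer_scores <- function(lateral, pairing, dorsal_ids = NULL) {
  lateral <- as.data.frame(lateral, stringsAsFactors = FALSE)
  need <- c("video_id", "final_score", "dba", "band")
  miss <- setdiff(need, names(lateral))
  if (length(miss))
    stop_validation("lateral results missing column(s): %s",
                    paste(miss, collapse = ", "))
  if (length(pairing) == 0L)
    return(lateral[0L, need])
  if (is.null(names(pairing)) || any(!nzchar(names(pairing))))
    stop_validation("`pairing` must be named by lateral video id")
  if (anyNA(pairing) || any(!nzchar(pairing)))
    stop_validation("pairing maps to a missing dorsal id")
  if (anyDuplicated(pairing))
    stop_validation("pairing is not injective: dorsal id '%s' used twice",
                    pairing[duplicated(pairing)][1L])
  if (!is.null(dorsal_ids)) {
    bad <- setdiff(pairing, dorsal_ids)
    if (length(bad))
      stop_validation("pairing maps to missing dorsal id(s): %s",
                      paste(bad, collapse = ", "))
  }
  paired <- lateral$video_id %in% names(pairing)
  if (any(!paired))
    warning(sprintf("dropping %d unpaired lateral video(s)", sum(!paired)))
  lat <- lateral[paired, , drop = FALSE]
  if (anyNA(lat$final_score))
    stop_validation("unresolved lateral score(s) cannot be transferred")
  data.frame(video_id = unname(pairing[lat$video_id]),
             final_score = lat$final_score, dba = lat$dba, band = lat$band,
             stringsAsFactors = FALSE)
}
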