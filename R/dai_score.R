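# Disease-activity-index (DAI) rubric for DSS-induced murine colitis:
# deterministic scoring of stool consistency, weight loss, fecal occult
# blood, and a four-criterion histology panel.

dai_stool_levels <- c(normal = 0L, soft = 1L, very_soft_semiformed = 2L,
                      liquid_or_sticky = 3L)
dai_blood_levels <- c(negative_2min = 0L, purple_after_10s = 1L,
                      light_purple_within_10s = 2L,
                      heavy_purple_within_10s = 3L)
dai_histology_fields <- c("histology_epithelium", "histology_edema",
                          "histology_crypt_loss", "histology_infiltration")

#' DAI category vocabularies
#'
#' @return list of the closed vocabularies and score ranges used by
#'   [score_components()].
#' @export
dai_vocabulary <- function() {
  list(stool = dai_stool_levels, blood = dai_blood_levels,
       weight_bins = c("0%" = 0L, "(0,5)%" = 1L, "[5,10)%" = 2L,
                       "[10,20)%" = 3L, ">=20%" = 4L),
       histology_fields = dai_histology_fields,
       histology_subscore_range = 0:3)
}

#' Score disease-activity-index components
#'
#' Maps each observation to its rubric scores: stool consistency 0--3, body
#' weight loss 0--4, fecal occult blood 0--3, and histology as the sum of
#' four 0--3 subscores (epithelial destruction, edema, crypt loss, mucosa
#' infiltration; 0--12 total). Weight-loss bins are lower-inclusive
#' half-open: 0 -> 0, (0,5) -> 1, \[5,10) -> 2, \[10,20) -> 3, >= 20 -> 4.
#' The total is the unweighted component sum (range 0--22).
#'
#' @param obs data.frame with columns `stool`, `weight_loss` (percent >= 0),
#'   `blood`, and the four histology subscore columns
#'   `histology_epithelium`, `histology_edema`, `histology_crypt_loss`,
#'   `histology_infiltration` (integers 0--3). Histology columns may be
#'   omitted entirely (scored 0).
#' @return data.frame with `stool_score`, `weight_score`, `blood_score`,
#'   `histology_score`, `total` (plus any `mouse_id`/`group` columns carried
#'   over).
#' @export
score_components <- function(obs) {
  stopifnot(is.data.frame(obs))
  req <- c("stool", "weight_loss", "blood")
  miss <- setdiff(req, names(obs))
  if (length(miss) > 0L)
    stop("observations missing column(s): ", paste(miss, collapse = ", "))
  stool <- as.character(obs$stool)
  bad <- which(!(stool %in% names(dai_stool_levels)))
  if (length(bad) > 0L)
    stop(sprintf("unknown stool category '%s' (row %d)", stool[bad[1]],
                 bad[1]))
  blood <- as.character(obs$blood)
  bad <- which(!(blood %in% names(dai_blood_levels)))
  if (length(bad) > 0L)
    stop(sprintf("unknown blood category '%s' (row %d)", blood[bad[1]],
                 bad[1]))
  wl <- as.numeric(obs$weight_loss)
  if (any(is.na(wl) | wl < 0))
    stop(sprintf("weight_loss must be >= 0 (row %d)",
                 which(is.na(wl) | wl < 0)[1]))
  weight_score <- ifelse(wl <= 0, 0L,
                  ifelse(wl < 5, 1L,
                  ifelse(wl < 10, 2L,
                  ifelse(wl < 20, 3L, 4L))))
  hist_present <- intersect(dai_histology_fields, names(obs))
  hist_score <- rep(0L, nrow(obs))
  for (f in hist_present) {
    h <- as.numeric(obs[[f]])
    if (any(is.na(h) | h < 0 | h > 3 | h != floor(h)))
      stop(sprintf("%s must be an integer in 0..3 (row %d)", f,
                   which(is.na(h) | h < 0 | h > 3 | h != floor(h))[1]))
    hist_score <- hist_score + as.integer(h)
  }
  carried <- intersect(c("mouse_id", "group"), names(obs))
  out <- cbind(obs[, carried, drop = FALSE],
               data.frame(stool_score = unname(dai_stool_levels[stool]),
                          weight_score = as.integer(weight_score),
                          blood_score = unname(dai_blood_levels[blood]),
                          histology_score = hist_score))
  out$total <- out$stool_score + out$weight_score + out$blood_score +
    out$histology_score
  out
}

#' Per-group DAI summary
#'
#' Mean and standard deviation of the total and each component, per group.
#'
#' @param scores output of [score_components()].
#' @param groups group labels, one per row of `scores` (defaults to a
#'   `group` column of `scores`).
#' @return data.frame, one row per group: n, mean/sd of each component and
#'   the total.
#' @export
cohort_summary <- function(scores, groups = scores$group) {
  stopifnot(is.data.frame(scores))
  if (is.null(groups)) stop("no group labels supplied")
  groups <- as.character(groups)
  comp <- c("stool_score", "weight_score", "blood_score", "histology_score",
            "total")
  out <- do.call(rbind, lapply(split(seq_len(nrow(scores)), groups),
    function(idx) {
      row <- data.frame(group = groups[idx[1]], n = length(idx))
      for (cn in comp) {
        row[[paste0(cn, "_mean")]] <- mean(scores[[cn]][idx])
        row[[paste0(cn, "_sd")]] <-
          if (length(idx) > 1L) stats::sd(scores[[cn]][idx]) else 0
      }
      row
    }))
  row.names(out) <- NULL
  out
}
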