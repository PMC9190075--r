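# Incremental cost-effectiveness analysis: pairwise ICERs, dominance and
# extended dominance, net monetary benefit.

#' Incremental cost-effectiveness ratio between two arms
#'
#' Two reporting conventions are supported. `"full"` divides the
#' full-precision differences. `"rounded"` first rounds the incremental cost
#' to whole pounds and the incremental QALYs to four decimal places -- the
#' published convention for this model's result tables, where arm means are
#' printed at exactly that precision -- and then divides. With incremental
#' QALYs of the order 0.0001-0.005, the rounded convention can move the ratio
#' appreciably; both are exposed so the choice is explicit.
#'
#' @param delta_cost Incremental cost (GBP).
#' @param delta_qaly Incremental QALYs.
#' @param convention `"full"` (default) or `"rounded"`.
#' @return The ICER in GBP per QALY, or `NA` when the (possibly rounded)
#'   incremental QALYs are zero.
#' @export
icer <- function(delta_cost, delta_qaly, convention = c("full", "rounded")) {
  convention <- match.arg(convention)
  if (convention == "rounded") {
    delta_cost <- round(delta_cost)
    delta_qaly <- round(delta_qaly, 4)
  }
  ifelse(delta_qaly == 0, NA_real_, delta_cost / delta_qaly)
}

#' Incremental analysis of each arm against a reference arm
#'
#' @param arms Data frame of arm results as returned by [evaluate_all()]
#'   (columns `strategy`, `mean_qaly`, `mean_cost`).
#' @param reference Strategy id of the reference arm (present in `arms`).
#' @param convention ICER convention passed to [icer()].
#' @return Data frame with one row per non-reference arm: `strategy`,
#'   `reference`, `delta_qaly`, `delta_cost` (full precision), `icer`, and
#'   `dominance` (`"dominant"` when cheaper and more effective,
#'   `"dominated"` when dearer and less effective, otherwise `"trade-off"`;
#'   a negative ICER is sign-ambiguous, so the annotation disambiguates).
#' @export
#' @examples
#' incremental_vs_reference(evaluate_all(default_parameters()), "no_screen")
incremental_vs_reference <- function(arms, reference = "no_screen",
                                     convention = c("full", "rounded")) {
  convention <- match.arg(convention)
  if (!(reference %in% arms$strategy))
    stop("reference strategy '", reference, "' is not among the arms", call. = FALSE)
  ref <- arms[arms$strategy == reference, ]
  others <- arms[arms$strategy != reference, , drop = FALSE]
  dq <- others$mean_qaly - ref$mean_qaly
  dc <- others$mean_cost - ref$mean_cost
  dominance <- ifelse(dq >= 0 & dc <= 0 & (dq > 0 | dc < 0), "dominant",
               ifelse(dq <= 0 & dc >= 0 & (dq < 0 | dc > 0), "dominated",
                      "trade-off"))
  data.frame(strategy = others$strategy, reference = reference,
             delta_qaly = dq, delta_cost = dc,
             icer = icer(dc, dq, convention),
             dominance = dominance, stringsAsFactors = FALSE)
}

#' Cost-effectiveness frontier by dominance and extended dominance
#'
#' Arms are sorted by ascending cost. Strictly dominated arms (another arm no
#' dearer and no less effective, with at least one strict inequality) are
#' removed first; arms with identical cost and QALYs are kept and flagged as
#' ties. Extended dominance then iteratively removes any interior arm whose
#' incremental ICER against its predecessor is not lower than the next
#' incremental ICER, until ICERs strictly increase along the frontier.
#'
#' @param arms Data frame of arm results (columns `strategy`, `mean_qaly`,
#'   `mean_cost`); at least two arms.
#' @param convention ICER convention for the reported adjacent ICERs.
#' @return List with `frontier` (data frame of retained arms in cost order
#'   with `icer_vs_previous`) and `status` (named character vector over all
#'   arms: `on_frontier`, `dominated`, `extended_dominated`, with ties
#'   marked `on_frontier_tie`).
#' @export
#' @examples
#' dominance_frontier(evaluate_all(default_parameters()))
dominance_frontier <- function(arms, convention = c("full", "rounded")) {
  convention <- match.arg(convention)
  stopifnot(nrow(arms) >= 2)
  status <- stats::setNames(rep("on_frontier", nrow(arms)), arms$strategy)

  for (i in seq_len(nrow(arms))) {
    for (j in seq_len(nrow(arms))) {
      if (i == j) next
      ci <- arms$mean_cost[i]; qi <- arms$mean_qaly[i]
      cj <- arms$mean_cost[j]; qj <- arms$mean_qaly[j]
      if (cj <= ci && qj >= qi && (cj < ci || qj > qi)) {
        status[arms$strategy[i]] <- "dominated"
        break
      }
    }
  }

  live <- arms[status[arms$strategy] != "dominated", , drop = FALSE]
  live <- live[order(live$mean_cost, -live$mean_qaly), , drop = FALSE]

  # flag exact ties (identical cost and QALYs survive strict dominance)
  dup <- duplicated(live[, c("mean_cost", "mean_qaly")]) |
    duplicated(live[, c("mean_cost", "mean_qaly")], fromLast = TRUE)
  status[live$strategy[dup]] <- "on_frontier_tie"

  repeat {
    if (nrow(live) <= 2) break
    ic <- c(NA_real_, diff(live$mean_cost) / diff(live$mean_qaly))
    drop_idx <- NA_integer_
    for (i in 2:(nrow(live) - 1)) {
      if (!is.na(ic[i]) && !is.na(ic[i + 1]) && ic[i] >= ic[i + 1]) {
        drop_idx <- i
        break
      }
    }
    if (is.na(drop_idx)) break
    status[live$strategy[drop_idx]] <- "extended_dominated"
    live <- live[-drop_idx, , drop = FALSE]
  }

  dq <- c(NA_real_, diff(live$mean_qaly))
  dc <- c(NA_real_, diff(live$mean_cost))
  live$icer_vs_previous <- c(NA_real_, icer(dc[-1], dq[-1], convention))
  rownames(live) <- NULL
  list(frontier = live, status = status)
}

#' Net monetary benefit
#'
#' @param qaly QALYs (scalar or vector).
#' @param cost Cost in GBP (scalar or vector).
#' @param lambda Willingness to pay per QALY (>= 0).
#' @return `lambda * qaly - cost`.
#' @export
#' @examples
#' net_monetary_benefit(0.7302, 1772, 20000)
net_monetary_benefit <- function(qaly, cost, lambda) {
  if (any(lambda < 0)) stop("lambda must be >= 0", call. = FALSE)
  lambda * qaly - cost
}
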