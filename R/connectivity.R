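#' Group-by-group synapse connection matrix
#'
#' Entry (s, t) is the summed synapse weight of connectors whose presynaptic
#' neuron belongs to source group s and postsynaptic neuron to target group
#' t, optionally restricted to a compartment. Neurons not covered by a
#' grouping fall into group `"other"`; the grand total always equals the
#' filtered connector weight sum (conservation).
#'
#' @param connectors A [connector_table()].
#' @param src_grouping,tgt_grouping Named character vectors mapping
#'   neuron_id to group label.
#' @param region_filter Optional character vector of compartment names; only
#'   rows in those compartments are aggregated.
#' @param drop_uncovered Drop rows whose pre or post neuron is in neither
#'   grouping (instead of mapping to `"other"`); default `FALSE`.
#' @return An integer matrix with class attribute `connection_matrix`;
#'   `attr(, "region_filter")` records the restriction.
#' @export
build_connection_matrix <- function(connectors, src_grouping, tgt_grouping,
                                    region_filter = NULL,
                                    drop_uncovered = FALSE) {
  rows <- connectors
  if (!is.null(region_filter)) {
    rows <- rows[!is.na(rows$compartment) &
                   rows$compartment %in% region_filter, , drop = FALSE]
  }
  src <- unname(src_grouping[rows$pre])
  tgt <- unname(tgt_grouping[rows$post])
  if (drop_uncovered) {
    keep <- !is.na(src) & !is.na(tgt)
    rows <- rows[keep, , drop = FALSE]
    src <- src[keep]; tgt <- tgt[keep]
  } else {
    src[is.na(src)] <- "other"
    tgt[is.na(tgt)] <- "other"
  }
  src_levels <- sort(unique(c(src_grouping, if (any(src == "other")) "other")))
  tgt_levels <- sort(unique(c(tgt_grouping, if (any(tgt == "other")) "other")))
  m <- matrix(0L, nrow = length(src_levels), ncol = length(tgt_levels),
              dimnames = list(src_levels, tgt_levels))
  if (nrow(rows) > 0L) {
    agg <- tapply(rows$weight,
                  list(factor(src, levels = src_levels),
                       factor(tgt, levels = tgt_levels)), sum)
    agg[is.na(agg)] <- 0
    m[] <- as.integer(agg)
  }
  structure(m, region_filter = region_filter, class = c("connection_matrix",
                                                        class(m)))
}

#' Normalise a connection matrix to its global maximum
#'
#' Every entry is divided by the largest entry, giving the "relative input
#' strength" scale of the heatmap displays (strongest connection = 1).
#' All-zero matrices are returned unchanged with a warning and
#' `attr(, "all_zero") = TRUE`.
#'
#' @param m A numeric matrix (typically from [build_connection_matrix()]).
#' @return A numeric matrix in `[0, 1]`.
#' @export
normalize_to_max <- function(m) {
  mx <- max(m)
  if (mx <= 0) {
    warning("connection matrix has no positive entry; returning zeros")
    out <- m * 0
    attr(out, "all_zero") <- TRUE
    return(out)
  }
  out <- unclass(m) / mx
  attr(out, "region_filter") <- attr(m, "region_filter")
  out
}

#' Input fractions by source-neuron group onto a target set
#'
#' For a set of target neurons, the fraction of their input synapses (rows
#' where they are postsynaptic) contributed via each target group, counted
#' outside the excluded compartments. With the default exclusion of the CX
#' compartments this is the "lateral input" breakdown: the sunburst sector
#' sizes. Fractions sum to 1 whenever any synapse survives the exclusion.
#'
#' Counting side: by default input synapses are the PSD-side rows of the
#' target neurons (any `kind`, the `post` column); set `count_side = "pre"`
#' to count the presynaptic partners' T-bar rows instead.
#'
#' @param connectors A [connector_table()].
#' @param tgt_grouping Named character vector: target neuron_id -> group
#'   (e.g. lineage of the FB large-field neuron).
#' @param exclude_regions Compartments excluded from the count (default:
#'   none; pass the CX compartment names for lateral inputs).
#' @param count_side `"post"` (default) or `"pre"`.
#' @return A data.frame `group`, `synapses`, `fraction`, sorted by
#'   decreasing fraction. Zero totals yield `NA` fractions with a warning.
#' @export
input_fraction_by_group <- function(connectors, tgt_grouping,
                                    exclude_regions = character(0),
                                    count_side = c("post", "pre")) {
  count_side <- match.arg(count_side)
  stopifnot(length(tgt_grouping) > 0L)
  rows <- connectors[connectors$post %in% names(tgt_grouping), , drop = FALSE]
  if (length(exclude_regions) > 0L) {
    rows <- rows[is.na(rows$compartment) |
                   !rows$compartment %in% exclude_regions, , drop = FALSE]
  }
  if (count_side == "pre") {
    rows <- rows[rows$kind == "TBAR", , drop = FALSE]
  }
  groups <- sort(unique(unname(tgt_grouping)))
  syn <- vapply(groups, function(g) {
    tgt <- names(tgt_grouping)[tgt_grouping == g]
    sum(rows$weight[rows$post %in% tgt])
  }, 0)
  total <- sum(syn)
  if (total == 0) {
    warning("no input synapses left after region exclusion")
    frac <- rep(NA_real_, length(groups))
  } else {
    frac <- syn / total
  }
  out <- data.frame(group = groups, synapses = syn, fraction = frac,
                    row.names = NULL)
  out[order(-out$synapses), ]
}

#' Per-neuron T-bar counts in a compartment
#'
#' Number of presynaptic release sites (kind `TBAR`, weight-summed) each
#' neuron forms in a compartment. PSD rows are excluded.
#'
#' @param connectors A [connector_table()].
#' @param neuron_set Character vector of neuron ids (all reported, absent
#'   neurons get 0).
#' @param region Compartment name(s).
#' @param grouping Optional named vector neuron_id -> group for ordering and
#'   the output column.
#' @return A data.frame `neuron_id`, `group`, `tbars`, sorted by group then
#'   decreasing count.
#' @export
tbar_counts <- function(connectors, neuron_set, region, grouping = NULL) {
  rows <- connectors[connectors$kind == "TBAR" &
                       !is.na(connectors$compartment) &
                       connectors$compartment %in% region &
                       connectors$pre %in% neuron_set, , drop = FALSE]
  counts <- vapply(neuron_set, function(n) {
    sum(rows$weight[rows$pre == n])
  }, 0)
  grp <- if (is.null(grouping)) rep(NA_character_, length(neuron_set)) else
    unname(grouping[neuron_set])
  out <- data.frame(neuron_id = neuron_set, group = grp,
                    tbars = as.integer(counts), row.names = NULL)
  out[order(out$group, -out$tbars, out$neuron_id), ]
}

#' ECDF of pairwise connection strengths
#'
#' Connection strength is the total synapse weight per ordered (pre, post)
#' neuron pair. Strengths are collected for pairs whose presynaptic neuron
#' is in `src_set`, within a compartment, and returned as the empirical CDF
#' `F(x) = #\{strengths <= x\} / N` (right-continuous).
#'
#' @param connectors A [connector_table()].
#' @param src_set Presynaptic neuron ids.
#' @param region Optional compartment restriction.
#' @return A list of class `pairwise_ecdf`: `strengths` (sorted), `ecdf`
#'   (a [stats::ecdf()]), `n_pairs`; `n_pairs == 0` flags an empty ECDF.
#' @export
pairwise_strength_ecdf <- function(connectors, src_set, region = NULL) {
  rows <- connectors[connectors$pre %in% src_set, , drop = FALSE]
  if (!is.null(region)) {
    rows <- rows[!is.na(rows$compartment) & rows$compartment %in% region, ,
                 drop = FALSE]
  }
  if (nrow(rows) == 0L) {
    return(structure(list(strengths = numeric(0), ecdf = NULL, n_pairs = 0L),
                     class = "pairwise_ecdf"))
  }
  strengths <- tapply(rows$weight, paste(rows$pre, rows$post, sep = "\r"),
                      sum)
  strengths <- sort(as.numeric(strengths))
  structure(list(strengths = strengths, ecdf = stats::ecdf(strengths),
                 n_pairs = length(strengths)),
            class = "pairwise_ecdf")
}

#' Dominant-source fraction per target group
#'
#' Given a connection matrix whose source groups split into two
#' super-groups (e.g. the two TuBu hemilineages), reports for every target
#' column the fraction of its synapses arriving from its dominant
#' super-group. A fraction of 1.0 for every target is the exclusivity
#' pattern (each target class driven by exactly one super-group).
#'
#' @param m A [build_connection_matrix()] result.
#' @param partition Named character vector: source group -> super-group
#'   (exactly 2 distinct super-groups).
#' @return A data.frame `target`, `dominant`, `fraction` (`NA` for all-zero
#'   columns).
#' @export
source_exclusivity <- function(m, partition) {
  supers <- unique(unname(partition))
  if (length(supers) != 2L) stop("partition must define exactly 2 super-groups")
  if (!all(rownames(m) %in% names(partition))) {
    stop("partition does not cover source groups: ",
         paste(setdiff(rownames(m), names(partition)), collapse = ", "))
  }
  sup <- unname(partition[rownames(m)])
  by_super <- rbind(colSums(m[sup == supers[1], , drop = FALSE]),
                    colSums(m[sup == supers[2], , drop = FALSE]))
  rownames(by_super) <- supers
  tot <- colSums(by_super)
  dom_i <- apply(by_super, 2, which.max)
  data.frame(
    target = colnames(m),
    dominant = ifelse(tot == 0, NA_character_, supers[dom_i]),
    fraction = ifelse(tot == 0, NA_real_,
                      by_super[cbind(dom_i, seq_along(tot))] / tot),
    row.names = NULL
  )
}

#' Shade weight of output synapses by upstream input strength
#'
#' Each output synapse of a neuron is weighted by that neuron's total input
#' from a set of upstream sources, normalised to the strongest
#' upstream-to-target connection — the shading used for projected synapse
#' maps. Neurons without any upstream record get weight 0 and are flagged.
#'
#' @param connectors Output-synapse rows (a [connector_table()]); weights
#'   are computed for each row's `pre` neuron.
#' @param upstream_matrix A [build_connection_matrix()] of upstream sources
#'   x target neurons (targets as individual neuron columns).
#' @return Numeric vector in `[0, 1]`, one weight per connector row;
#'   `attr(, "missing_upstream")` lists flagged neurons.
#' @export
synapse_weight_by_upstream <- function(connectors, upstream_matrix) {
  per_target <- colSums(upstream_matrix)
  if (max(per_target) <= 0) stop("upstream matrix has no positive entry")
  strength <- per_target[connectors$pre]
  missing <- unique(connectors$pre[is.na(strength)])
  strength[is.na(strength)] <- 0
  w <- unname(strength) / max(per_target)
  attr(w, "missing_upstream") <- missing
  w
}
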