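#' Construct / validate a connector table
#'
#' A connector table holds one row per synaptic contact (an ordered
#' `pre -> post` link). The `kind` column records which anatomical site the
#' row's coordinates refer to: `"TBAR"` for the presynaptic release site of
#' the `pre` neuron, `"PSD"` for the postsynaptic density of the `post`
#' neuron. Aggregated tables may carry an integer `weight` >= 1 (number of
#' synapses the row stands for); every downstream count sums weights.
#'
#' @param df A data.frame with columns `synapse_id`, `pre`, `post`, `kind`,
#'   `x`, `y`, `z` (nm) and optionally `compartment` and `weight`.
#' @return The validated data.frame with class `connector_table` prepended;
#'   autapse rows (`pre == post`) are flagged in an `autapse` column.
#' @export
connector_table <- function(df) {
  required <- c("synapse_id", "pre", "post", "kind", "x", "y", "z")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("connector table missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)
  df$pre <- as.character(df$pre)
  df$post <- as.character(df$post)
  df$kind <- toupper(as.character(df$kind))
  bad_kind <- setdiff(unique(df$kind), c("TBAR", "PSD"))
  if (length(bad_kind) > 0L) {
    stop("invalid connector kind(s): ", paste(bad_kind, collapse = ", "),
         " (must be TBAR or PSD)")
  }
  if (is.null(df$weight)) df$weight <- 1L
  w <- df$weight
  if (any(!is.finite(w)) || any(w != round(w)) || any(w < 1)) {
    stop("connector weight must be an integer >= 1")
  }
  df$weight <- as.integer(round(w))
  if (is.null(df$compartment)) df$compartment <- NA_character_
  df$compartment <- as.character(df$compartment)
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z")])))) {
    stop("non-finite connector coordinates")
  }
  df$autapse <- df$pre == df$post
  class(df) <- c("connector_table", "data.frame")
  df
}

#' Read a synapse/connector table from CSV
#'
#' The CSV dialect is comma-separated, header row, UTF-8. Column names can be
#' remapped via `columns` for foreign exports. Unknown compartment names are
#' preserved verbatim; validation of kinds and weights is strict.
#'
#' @param path CSV path.
#' @param columns Named character vector mapping canonical names
#'   (`synapse_id`, `pre`, `post`, `kind`, `x`, `y`, `z`, `compartment`,
#'   `weight`) to the file's column names; defaults to identity.
#' @return A [connector_table()].
#' @export
read_synapse_table <- function(path, columns = NULL) {
  if (!file.exists(path)) stop("synapse table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!is.null(columns)) {
    for (canon in names(columns)) {
      src <- columns[[canon]]
      if (!src %in% names(raw)) {
        stop("mapped column '", src, "' (for ", canon, ") absent from ", path)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  connector_table(raw)
}

#' Write a connector table to CSV
#'
#' @param connectors A [connector_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_synapse_table <- function(connectors, path) {
  out <- as.data.frame(connectors)
  out$autapse <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Connector rows touching a neuron
#'
#' A neuron's connectors are the rows where it is the presynaptic neuron
#' (its T-bars) or the postsynaptic neuron (its PSDs).
#'
#' @param connectors A [connector_table()].
#' @param neuron_id Neuron identifier.
#' @return The matching rows.
#' @export
neuron_connectors <- function(connectors, neuron_id) {
  connectors[connectors$pre == neuron_id | connectors$post == neuron_id, ,
             drop = FALSE]
}

#' Label connector rows with their compartment
#'
#' Fills (or overwrites) the `compartment` column by point-in-region lookup
#' against a compartment model.
#'
#' @param connectors A [connector_table()].
#' @param model A [compartment_model()].
#' @param overwrite Re-label rows that already carry a compartment
#'   (default `TRUE`).
#' @return The relabelled [connector_table()].
#' @export
label_compartments <- function(connectors, model, overwrite = TRUE) {
  todo <- if (overwrite) rep(TRUE, nrow(connectors)) else is.na(connectors$compartment)
  if (any(todo)) {
    pts <- as.matrix(connectors[todo, c("x", "y", "z")])
    connectors$compartment[todo] <- region_of(pts, model)
  }
  connectors
}
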