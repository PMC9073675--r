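#' Read a replicate-outcome assay table from CSV
#'
#' Reads a tidy assay table (one row per line x replicate) with columns
#' `line_id`, `replicate_id`, `sterile_generation` (empty when censored),
#' `censored` (0/1), and optionally `failure_mode`. Tables exported from
#' other sources can be adapted with a column mapping: a named list (or a
#' YAML file containing one) whose names are the canonical column names and
#' whose values are the source column names, optionally with a `horizon`
#' entry.
#'
#' @param path CSV file path.
#' @param column_map Optional named list or YAML file path mapping
#'   canonical names to source column names (e.g.
#'   `list(line_id = "strain", sterile_generation = "gen_sterile")`).
#' @param horizon Assay horizon in generations; if omitted, taken from the
#'   column map or left to downstream functions to require.
#' @return Data frame with the canonical columns and a `horizon` attribute
#'   when known.
#' @export
read_assay_table <- function(path, column_map = NULL, horizon = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(x) == 0) stop("assay table is empty: ", path)
  if (is.character(column_map) && length(column_map) == 1L) {
    column_map <- yaml::read_yaml(column_map)
  }
  if (!is.null(column_map)) {
    horizon <- horizon %||% column_map$horizon
    column_map$horizon <- NULL
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(x)) {
        stop("mapped column '", src, "' not found in ", path)
      }
      names(x)[names(x) == src] <- canon
    }
  }
  need <- c("line_id", "replicate_id", "sterile_generation", "censored")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("assay table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.null(horizon)) attr(x, "horizon") <- as.integer(horizon)
  x
}

#' Write a replicate-outcome assay table to CSV
#'
#' @param x Assay table (e.g. from [generate_assay_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(x, path) {
  cols <- c("line_id", "replicate_id", "sterile_generation", "censored",
            "failure_mode")
  cols <- intersect(cols, names(x))
  utils::write.csv(as.data.frame(x)[, cols], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

# Build a synthetic_config from a YAML file of the form:
#   design: {n_lines: 95, reps_per_line: 3, assay_generations: 21, label: wi}
#   mixture: {strong: 0.06, wild_type: 0.94}
#   model: {strong: {mu: 5}}          # optional per-class overrides
#   seed: 42                          # optional
config_from_yaml <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (is.null(y$design) || is.null(y$mixture)) {
    stop("config must contain 'design' and 'mixture' sections")
  }
  d <- y$design
  design <- assay_design(d$n_lines, d$reps_per_line, d$assay_generations,
                         d$label %||% "assay")
  model <- if (is.null(y$model)) sterility_model() else
    do.call(sterility_model, y$model)
  synthetic_config(design, unlist(y$mixture), model,
                   seed = seed %||% y$seed)
}
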