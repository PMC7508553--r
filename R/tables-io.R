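# Table readers/writers with schema validation.
#
# CSV dialect: header row, UTF-8, "." decimal, no index column. Doubles are
# written with 17 significant digits (%.17g), so write-then-read is the
# identity on values.

.schemas <- list(
  lineage = list(
    cols = c("lineage_id", "parent_f", "embryo_f", "l4_f", "adult_f"),
    freq_cols = c("parent_f", "embryo_f", "l4_f", "adult_f"),
    class = "lineage_table"),
  competition = list(
    cols = c("line_id", "generation", "competed", "pooled_f",
             "het_fraction", "n_genotyped", "terminated"),
    freq_cols = c("pooled_f", "het_fraction"),
    class = "competition_table"),
  droplets = list(
    cols = c("reaction_id", "n_total", "n_neg", "n_wt_only",
             "n_mut_only", "n_double"),
    freq_cols = character(0),
    class = "droplet_table"))

#' Read a validated pipeline table
#'
#' @param path CSV file path.
#' @param schema One of `"lineage"`, `"competition"`, `"droplets"`.
#' @return A validated data.frame carrying the schema class.
#' @export
read_table <- function(path, schema = c("lineage", "competition", "droplets")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sc <- .schemas[[schema]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(sc$cols, names(df))
  if (length(missing))
    stop("schema '", schema, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[sc$cols]
  for (cl in sc$freq_cols) {
    bad <- which(is.finite(df[[cl]]) & (df[[cl]] < 0 | df[[cl]] > 1))
    if (length(bad))
      stop("column ", cl, ": frequency out of [0, 1] at row ", bad[1],
           call. = FALSE)
  }
  if (schema == "droplets") {
    parts <- df$n_neg + df$n_wt_only + df$n_mut_only + df$n_double
    if (any(parts != df$n_total))
      stop("droplet classes do not partition n_total at row ",
           which(parts != df$n_total)[1], call. = FALSE)
  }
  ml_log("read ", nrow(df), " row(s) from ", path, " [", schema, "]")
  structure(df, class = c(sc$class, "data.frame"))
}

#' Write a pipeline table
#'
#' @param df Data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  ml_log("wrote ", nrow(df), " row(s) to ", path)
  invisible(path)
}

#' Read droplet-count records and quantify each reaction
#'
#' @param path Droplets CSV (schema `droplets`).
#' @param droplet_vol,dilution,lysis_vol,n_individuals Passed to
#'   [quantify_droplets].
#' @return data.frame of one [quantify_droplets] record per reaction.
#' @export
quantify_table <- function(path, droplet_vol = 0.00085, dilution = 1,
                           lysis_vol = 1, n_individuals = 1) {
  df <- read_table(path, "droplets")
  recs <- lapply(seq_len(nrow(df)), function(i) {
    q <- quantify_droplets(
      droplet_counts(df$n_neg[i], df$n_wt_only[i], df$n_mut_only[i],
                     df$n_double[i]),
      droplet_vol, dilution, lysis_vol, n_individuals)
    data.frame(reaction_id = df$reaction_id[i],
               lambda_wt = q$lambda_wt, lambda_mut = q$lambda_mut,
               freq = q$freq,
               copies_per_individual_wt = q$copies_per_individual_wt,
               copies_per_individual_mut = q$copies_per_individual_mut)
  })
  do.call(rbind, recs)
}
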