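#' Compute the suction specialization index (SSI)
#'
#' For each taxon the SSI is the mean score over the suction-related
#' characters (`char_mean`), with the sum of scores (`char_sum`) kept as an
#' alternative composite. The adjusted SSI averages only the
#' osteological/dentition characters, excluding the soft-tissue characters
#' (round mouth, throat grooves); it emulates what is observable in fossils.
#' Score spread per taxon is summarized by the sample standard deviation
#' (n - 1 denominator) over the characters entering `char_mean`, and over the
#' adjusted set (`adjusted_sd`).
#'
#' Missing scores are handled by `policy`: `"renormalize"` (default) averages
#' over the available characters and records `n_used`; `"error"` refuses any
#' missing score.
#'
#' @param x a [character_matrix()]
#' @param policy `"renormalize"` or `"error"`
#' @param flag_threshold optional numeric; if given, an extra logical column
#'   `strong_suction` marks taxa with `char_mean` strictly above it (the
#'   conventional reading is that values above 1.00 constitute strong
#'   evidence of suction specialization).
#' @return a data frame of class `"ssi_table"` with columns `taxon`,
#'   `char_sum`, `char_mean`, `adjusted_ssi`, `score_sd`, `adjusted_sd`,
#'   `n_used`, `n_used_adjusted`.
#' @examples
#' s <- matrix(c(rep(0, 9), 1), 1, 10,
#'   dimnames = list("t1", paste0("c", 1:10)))
#' compute_ssi(character_matrix(s))  # char_mean 0.1, score_sd 0.316
#' @export
compute_ssi <- function(x, policy = c("renormalize", "error"),
                        flag_threshold = NULL) {
  stopifnot(inherits(x, "character_matrix"))
  policy <- match.arg(policy)
  s <- x$scores
  if (policy == "error" && anyNA(s)) {
    bad <- which(is.na(s), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing score under policy='error': taxon '%s', character '%s'",
                 rownames(s)[bad[1L]], colnames(s)[bad[2L]]))
  }
  osteo <- x$char_class == "osteo_dental"
  n_used <- rowSums(!is.na(s))
  if (any(n_used == 0L)) {
    stop("no usable characters for taxon: ",
         rownames(s)[which(n_used == 0L)[1L]])
  }
  so <- s[, osteo, drop = FALSE]
  n_used_adj <- rowSums(!is.na(so))
  sd_row <- function(m) apply(m, 1L, stats::sd, na.rm = TRUE)
  out <- data.frame(
    taxon = rownames(s),
    char_sum = rowSums(s, na.rm = TRUE),
    char_mean = rowMeans(s, na.rm = TRUE),
    adjusted_ssi = ifelse(n_used_adj > 0L, rowMeans(so, na.rm = TRUE), NA_real_),
    score_sd = sd_row(s),
    adjusted_sd = ifelse(n_used_adj > 1L, sd_row(so), NA_real_),
    n_used = as.integer(n_used),
    n_used_adjusted = as.integer(n_used_adj),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(flag_threshold)) {
    out$strong_suction <- out$char_mean > flag_threshold
  }
  class(out) <- c("ssi_table", "data.frame")
  out
}

#' Rank taxa by suction specialization
#'
#' @param table an `ssi_table` from [compute_ssi()]
#' @return character vector of taxon names sorted by decreasing `char_mean`;
#'   ties broken alphabetically.
#' @export
rank_taxa <- function(table) {
  stopifnot(inherits(table, "ssi_table"), nrow(table) > 0L)
  table$taxon[order(-table$char_mean, table$taxon)]
}
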