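#' Construct a validated ordinal character matrix
#'
#' The central trait container of the package: a taxon x character grid of
#' ordinal scores on the 0--3 scale used for ecomorphological scoring
#' (0 = never present, 1 = weakly present, 2 = somewhat present,
#' 3 = strongly present). Characters carry a class tag separating
#' osteological/dentition characters (observable in fossils) from soft-tissue
#' characters, and strictly binary characters (e.g. throat grooves) are
#' restricted to scores \{0, 3\}.
#'
#' @param scores numeric matrix or data frame, taxa in rows (rownames or the
#'   first column), characters in columns (colnames). Values in \[0, 3\] or
#'   `NA` for missing.
#' @param char_class character vector, one entry per character, each
#'   `"osteo_dental"` or `"soft_tissue"`. Defaults to all `"osteo_dental"`.
#'   May be named by character.
#' @param binary logical vector (or character vector of column names) marking
#'   characters whose only allowed scores are 0 and 3.
#' @return an object of class `"character_matrix"`: a list with elements
#'   `scores` (numeric matrix with taxon rownames), `char_class`, `binary`.
#' @examples
#' m <- character_matrix(matrix(c(0, 3, 1, 2), 2, 2,
#'   dimnames = list(c("A", "B"), c("c1", "c2"))))
#' taxa(m)
#' @export
character_matrix <- function(scores, char_class = NULL, binary = NULL) {
  if (is.data.frame(scores)) {
    if (!is.numeric(as.matrix(scores[, , drop = FALSE])) &&
        !all(vapply(scores, is.numeric, logical(1)))) {
      first_chr <- !is.numeric(scores[[1L]])
      if (first_chr) {
        rn <- as.character(scores[[1L]])
        scores <- as.matrix(scores[, -1L, drop = FALSE])
        rownames(scores) <- rn
      }
    }
    scores <- as.matrix(scores)
  }
  if (!is.numeric(scores)) stop("scores must be numeric")
  if (is.null(rownames(scores))) stop("taxon names required as rownames")
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("char", seq_len(ncol(scores)))
  }
  nc <- ncol(scores)
  if (is.null(char_class)) char_class <- rep("osteo_dental", nc)
  if (!is.null(names(char_class))) {
    char_class <- char_class[colnames(scores)]
  }
  char_class <- rep_len(as.character(char_class), nc)
  if (is.character(binary)) binary <- colnames(scores) %in% binary
  if (is.null(binary)) binary <- rep(FALSE, nc)
  binary <- rep_len(as.logical(binary), nc)
  obj <- structure(
    list(scores = scores, char_class = char_class, binary = binary),
    class = "character_matrix"
  )
  validate_character_matrix(obj)
  obj
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf(
    "character_matrix: %d taxa x %d characters (%d soft-tissue, %d binary), %d missing\n",
    nrow(x$scores), ncol(x$scores), sum(x$char_class == "soft_tissue"),
    sum(x$binary), sum(is.na(x$scores))
  ))
  invisible(x)
}

#' @rdname character_matrix
#' @param x a `character_matrix`
#' @export
taxa <- function(x) rownames(x$scores)

#' @rdname character_matrix
#' @export
characters <- function(x) colnames(x$scores)

#' Validate a character matrix
#'
#' Checks the score-range invariant (each score in \[0, 3\] or missing), the
#' binary-character rule (only 0, 3, or missing), taxon uniqueness, and that
#' at least one character is present. Violations are reported with their
#' taxon/character cell context.
#'
#' @param x a `character_matrix`
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_character_matrix <- function(x) {
  s <- x$scores
  if (ncol(s) < 1L) stop("at least one character required")
  if (anyDuplicated(normalize_taxon(rownames(s)))) {
    dup <- rownames(s)[duplicated(normalize_taxon(rownames(s)))]
    stop("duplicate taxa: ", paste(unique(dup), collapse = ", "))
  }
  if (length(x$char_class) != ncol(s) || length(x$binary) != ncol(s)) {
    stop("char_class and binary must have one entry per character")
  }
  if (!all(x$char_class %in% c("osteo_dental", "soft_tissue"))) {
    stop("char_class entries must be 'osteo_dental' or 'soft_tissue'")
  }
  bad <- which(!is.na(s) & (s < 0 | s > 3), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "score out of range [0, 3]: taxon '%s', character '%s', value %g",
      rownames(s)[bad[1L, 1L]], colnames(s)[bad[1L, 2L]],
      s[bad[1L, , drop = FALSE]]
    ))
  }
  for (j in which(x$binary)) {
    v <- s[, j]
    off <- which(!is.na(v) & !(v %in% c(0, 3)))
    if (length(off) > 0L) {
      stop(sprintf(
        paste0("binary character '%s' admits only scores 0 (never present) ",
               "or 3 (strongly present); taxon '%s' has %g"),
        colnames(s)[j], rownames(s)[off[1L]], v[off[1L]]
      ))
    }
  }
  invisible(x)
}

#' Normalize taxon names for matching
#'
#' Tip labels in published trees and taxon names in trait tables routinely
#' differ in underscore-vs-space and letter case. Matching everywhere in the
#' package is done on the normalized form (lowercase, runs of spaces and
#' underscores collapsed to a single underscore); display names are preserved.
#'
#' @param x character vector of names
#' @return normalized character vector
#' @export
normalize_taxon <- function(x) {
  tolower(gsub("[ _]+", "_", trimws(x)))
}

.sep_for <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a character matrix from CSV or TSV
#'
#' The header row names the characters and the first column names the taxa.
#' The dialect (comma vs tab) is chosen from the file extension.
#'
#' @param path file path (`.csv` comma-separated, `.tsv`/`.txt` tab-separated)
#' @inheritParams character_matrix
#' @return a validated [character_matrix()]
#' @export
read_character_matrix <- function(path, char_class = NULL, binary = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  rn <- as.character(df[[1L]])
  m <- df[, -1L, drop = FALSE]
  for (j in seq_along(m)) {
    v <- m[[j]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "" & toupper(v) != "NA")
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric score: taxon '%s', character '%s', value '%s'",
                     rn[bad[1L]], colnames(m)[j], v[bad[1L]]))
      }
      m[[j]] <- vn
    }
  }
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  rownames(m) <- rn
  character_matrix(m, char_class = char_class, binary = binary)
}

#' Write a character matrix to CSV or TSV
#'
#' @param x a `character_matrix`
#' @param path output path; dialect chosen from the extension
#' @return `path`, invisibly
#' @export
write_character_matrix <- function(x, path) {
  df <- data.frame(taxon = taxa(x), x$scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .sep_for(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a taxon-to-feeding-mode label table
#'
#' Two columns: taxon, label. Labels are matched case-insensitively against
#' the two feeding-mode levels, `Suction` (capture suction specialists) and
#' `Other` (raptorial and multimodal feeders).
#'
#' @param path CSV/TSV file path
#' @return named character vector mapping taxon name to `"Suction"`/`"Other"`
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  label_table(as.character(df[[1L]]), as.character(df[[2L]]))
}

#' @rdname read_label_table
#' @param taxa_names character vector of taxon names
#' @param modes character vector of feeding-mode labels (case-insensitive)
#' @export
label_table <- function(taxa_names, modes) {
  if (anyDuplicated(normalize_taxon(taxa_names))) {
    stop("duplicate taxon in label table: ",
         taxa_names[duplicated(normalize_taxon(taxa_names))][1L])
  }
  lv <- c(suction = "Suction", other = "Other")
  key <- tolower(trimws(modes))
  unknown <- !(key %in% names(lv))
  if (any(unknown)) {
    stop(sprintf("unknown feeding-mode label '%s' (allowed: Suction, Other)",
                 modes[which(unknown)[1L]]))
  }
  stats::setNames(unname(lv[key]), taxa_names)
}

#' Write a labelled label table
#' @param labels named vector as returned by [read_label_table()]
#' @param path output path
#' @export
write_label_table <- function(labels, path) {
  utils::write.table(
    data.frame(taxon = names(labels), mode = unname(labels)),
    path, sep = .sep_for(path), row.names = FALSE, quote = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Write a stage report as JSON
#'
#' All stage outputs serialize to structured JSON (numbers unrounded) so that
#' a written report re-read with [read_report()] reproduces the in-memory
#' values: exactly for integers, to at least 12 significant digits for
#' doubles.
#'
#' @param result any stage output (list-like; S3 classes are unclassed)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report <- function(result, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(.unclass_deep(result), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null",
                       force = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, .unclass_deep)
  }
  if (!is.null(attr(x, "class")) && !is.data.frame(x) && !is.matrix(x)) {
    attr(x, "class") <- NULL
  }
  x
}
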