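#' Read a TPS landmark file
#'
#' Parses the landmark-file dialect written by common 2-D digitizers: records
#' begin with `LM=<k>` followed by k whitespace-separated coordinate lines,
#' optionally followed by `ID=`, `IMAGE=` (ignored) and `SCALE=` lines. A
#' `SCALE=` factor multiplies the record's coordinates. CRLF and LF line
#' endings are both accepted. All records in one file must share the same
#' landmark count k.
#'
#' @param path path to a TPS file.
#' @param group optional named character vector mapping specimen ids to group
#'   labels; unmatched ids get `NA`.
#' @return A list of [landmark_config()] objects, one per record.
#' @seealso [write_tps()]
#' @export
read_tps <- function(path, group = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  configs <- list()
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE))
      stop("line ", i, ": expected 'LM=<count>' record header, got '", ln, "'")
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", ln, ignore.case = TRUE)))
    if (is.na(k) || k < 1L)
      stop("line ", i, ": malformed landmark count in '", ln, "'")
    rec <- rec + 1L
    i <- i + 1L
    coords <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      if (i > length(lines))
        stop("record ", rec, ": file ends before ", k, " coordinate lines")
      fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(fields) != 2L || grepl("=", lines[i], fixed = TRUE))
        stop("line ", i, ": expected 2 coordinates, got '", trimws(lines[i]), "'")
      xy <- suppressWarnings(as.numeric(fields))
      if (any(is.na(xy)))
        stop("line ", i, ": non-numeric coordinate '", trimws(lines[i]), "'")
      coords[j, ] <- xy
      i <- i + 1L
    }
    id <- paste0("specimen_", rec)
    scale <- 1
    while (i <= length(lines) && grepl("=", lines[i], fixed = TRUE) &&
           !grepl("^LM\\s*=", trimws(lines[i]), ignore.case = TRUE)) {
      kv <- trimws(lines[i])
      if (grepl("^ID\\s*=", kv, ignore.case = TRUE)) {
        id <- trimws(sub("^ID\\s*=", "", kv, ignore.case = TRUE))
      } else if (grepl("^SCALE\\s*=", kv, ignore.case = TRUE)) {
        scale <- suppressWarnings(as.numeric(sub("^SCALE\\s*=", "", kv, ignore.case = TRUE)))
        if (is.na(scale)) stop("line ", i, ": malformed SCALE value")
      }
      # IMAGE= and other keys are ignored
      i <- i + 1L
    }
    grp <- if (!is.null(group) && id %in% names(group)) group[[id]] else NA_character_
    configs[[rec]] <- landmark_config(coords * scale, id, grp)
  }
  ks <- vapply(configs, `[[`, integer(1), "k")
  if (length(unique(ks)) > 1L)
    stop("records with differing landmark counts in one file: ",
         paste(unique(ks), collapse = ", "))
  configs
}

#' Write landmark configurations to a TPS file
#'
#' Emits the dialect accepted by [read_tps()]: `LM=`, coordinate rows, `ID=`.
#' All configurations must share the same landmark count.
#'
#' @param configs list of [landmark_config()] objects (may be empty).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tps <- function(configs, path) {
  if (length(configs)) check_landmark_set(configs)
  out <- character(0)
  for (cfg in configs) {
    out <- c(out,
             paste0("LM=", cfg$k),
             apply(cfg$coords, 1, function(r)
               paste(formatC(r, format = "g", digits = 17), collapse = " ")),
             paste0("ID=", cfg$specimen_id))
  }
  writeLines(out, path)
  invisible(path)
}

#' Character matrix of discrete morphological states
#'
#' Taxa by characters matrix of unordered multistate symbols `0`..`9` with
#' `?` for missing data.
#'
#' @param states character matrix (taxa x characters) of single-character
#'   symbols; rownames are taxon names.
#' @param character_labels optional character vector of length `ncol(states)`.
#' @return An object of class `character_matrix` with fields `taxa`, `states`,
#'   `n_chars`, `character_labels`.
#' @export
character_matrix <- function(states, character_labels = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "character"
  if (is.null(rownames(states)))
    stop("states must have taxon names as rownames")
  taxa <- rownames(states)
  if (anyDuplicated(taxa)) stop("duplicate taxon names")
  ok <- states %in% c(as.character(0:9), "?")
  if (!all(ok))
    stop("invalid state symbols: ",
         paste(unique(states[!ok]), collapse = ", "),
         " (allowed: 0-9 and '?')")
  scored <- colSums(states != "?")
  if (any(scored == 0))
    stop("character(s) with no scored taxon: ",
         paste(which(scored == 0), collapse = ", "))
  if (!is.null(character_labels) && length(character_labels) != ncol(states))
    stop("character_labels length mismatch")
  structure(
    list(taxa = taxa, states = unname(states), n_chars = ncol(states),
         character_labels = character_labels),
    class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("<character_matrix>", length(x$taxa), "taxa x", x$n_chars, "characters;",
      sum(x$states == "?"), "missing cells\n")
  invisible(x)
}

#' Read a NEXUS character matrix
#'
#' Reads the DATA/CHARACTERS subset of NEXUS needed for morphological
#' matrices: a `DIMENSIONS` command (`NTAX`, `NCHAR`), an optional `FORMAT`
#' command with a `MISSING=` symbol (normalized to `?`), and a non-interleaved
#' `MATRIX` block. Taxon order is preserved.
#'
#' @param path path to a NEXUS file.
#' @return A [character_matrix()].
#' @export
read_nexus_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  txt <- paste(sub("\r$", "", lines), collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt)  # strip comments
  dim_m <- regmatches(txt, regexpr("(?i)DIMENSIONS[^;]*;", txt, perl = TRUE))
  if (!length(dim_m)) stop("no DIMENSIONS command found")
  ntax <- as.integer(sub(".*(?i)NTAX\\s*=\\s*([0-9]+).*", "\\1", dim_m, perl = TRUE))
  nchar_ <- as.integer(sub(".*(?i)NCHAR\\s*=\\s*([0-9]+).*", "\\1", dim_m, perl = TRUE))
  if (is.na(ntax) || is.na(nchar_))
    stop("DIMENSIONS must declare NTAX and NCHAR")
  missing_sym <- "?"
  fmt_m <- regmatches(txt, regexpr("(?i)FORMAT[^;]*;", txt, perl = TRUE))
  if (length(fmt_m) && grepl("(?i)MISSING\\s*=\\s*\\S", fmt_m, perl = TRUE))
    missing_sym <- sub(".*(?i)MISSING\\s*=\\s*(\\S).*", "\\1", fmt_m, perl = TRUE)
  mat_m <- regmatches(txt, regexpr("(?i)MATRIX(.|\n)*?;", txt, perl = TRUE))
  if (!length(mat_m)) stop("no MATRIX block found")
  body <- sub("^(?i)MATRIX", "", mat_m, perl = TRUE)
  body <- sub(";\\s*$", "", body)
  rows <- trimws(strsplit(body, "\n")[[1]])
  rows <- rows[rows != ""]
  if (length(rows) != ntax)
    stop("MATRIX has ", length(rows), " taxon rows but NTAX=", ntax)
  taxa <- character(ntax)
  states <- matrix(NA_character_, ntax, nchar_)
  for (i in seq_len(ntax)) {
    parts <- strsplit(rows[i], "\\s+")[[1]]
    if (length(parts) < 2) stop("malformed MATRIX row: '", rows[i], "'")
    taxa[i] <- gsub("^'|'$", "", parts[1])
    symbols <- strsplit(paste(parts[-1], collapse = ""), "")[[1]]
    if (length(symbols) != nchar_)
      stop("taxon '", taxa[i], "' has ", length(symbols),
           " states but NCHAR=", nchar_)
    states[i, ] <- symbols
  }
  states[states == missing_sym] <- "?"
  rownames(states) <- taxa
  character_matrix(states)
}

#' Write a character matrix as NEXUS
#'
#' @param cm a [character_matrix()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_nexus_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "character_matrix"))
  name_w <- max(nchar(cm$taxa))
  rows <- sprintf("    %-*s  %s", name_w, cm$taxa,
                  apply(cm$states, 1, paste, collapse = ""))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(cm$taxa), cm$n_chars),
    "  FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS=\"0123456789\";",
    "  MATRIX",
    rows,
    "  ;",
    "END;"), path)
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin validated wrappers around ape's Newick parser and serializer.
#' Support values stored as internal node labels are accepted.
#'
#' @param text a Newick string, or a path when `file = TRUE`.
#' @param file whether `text` names a file.
#' @return `read_newick()`: an ape `phylo` object; `write_newick()`: a Newick
#'   string (invisibly the path when `path` is given).
#' @export
read_newick <- function(text, file = FALSE) {
  tr <- tryCatch(
    if (file) ape::read.tree(text) else ape::read.tree(text = text),
    error = function(e) stop("invalid Newick: ", conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("invalid Newick: parser returned no tree")
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in tree")
  tr
}

#' @rdname read_newick
#' @param tree an ape `phylo` object.
#' @param path optional output path; when `NULL` the string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a craniodental measurement table
#'
#' CSV with a header of variable names and one row per specimen. Required
#' columns `specimen_id` and `group`; remaining columns are numeric linear
#' measurements in mm. Blank cells become missing; all present values must be
#' positive.
#'
#' @param path path to a CSV file (RFC-4180, UTF-8, '.' decimal).
#' @return A `data.frame` of class `measurement_table`.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  measurement_table(df)
}

#' Validate a data frame as a measurement table
#'
#' @param df data frame with `specimen_id`, `group` and numeric columns.
#' @return The validated `data.frame` with class `measurement_table` prepended.
#' @export
measurement_table <- function(df) {
  if (!all(c("specimen_id", "group") %in% names(df)))
    stop("measurement table needs 'specimen_id' and 'group' columns")
  if (anyDuplicated(names(df))) stop("duplicate variable names")
  if (anyDuplicated(df$specimen_id))
    stop("duplicate specimen_id: ",
         paste(unique(df$specimen_id[duplicated(df$specimen_id)]), collapse = ", "))
  vars <- setdiff(names(df), c("specimen_id", "group"))
  for (v in vars) {
    x <- df[[v]]
    if (is.character(x)) x[x == ""] <- NA
    x <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad))
      stop("non-positive measurement in variable '", v, "', row(s) ",
           paste(bad, collapse = ", "))
    df[[v]] <- x
  }
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' @rdname read_measurements
#' @param df a `measurement_table`.
#' @param path output path.
#' @export
write_measurements <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
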