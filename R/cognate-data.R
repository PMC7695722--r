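#' Multistate cognate datasets
#'
#' A `cognate_dataset` holds a lexical cognacy table: for each language and
#' concept (e.g. a Swadesh-list meaning), the set of cognate classes that
#' language attests for the concept, each with a loanword flag. A
#' (language, concept) pair with no rows is a missing datum; a pair with two
#' classes is a synonym. Tip dates (ka BP; 0 for extant languages) ride along
#' for downstream tip-dated inference.
#'
#' @param entries a data frame with columns `language`, `concept`,
#'   `cognate_class` and (optionally) logical `is_loan`; one row per attested
#'   word.
#' @param tip_dates optional data frame with columns `language`, `age_ka`, or
#'   a named numeric vector; languages not listed are taken as extant (0 ka).
#' @param languages,concepts optional orderings/supersets of the languages and
#'   concepts in `entries` (a language may lack rows entirely).
#' @param excluded_taxa character vector of languages already dropped by
#'   curation (bookkeeping only).
#' @return an object of class `cognate_dataset`.
#' @export
cognate_dataset <- function(entries, tip_dates = NULL, languages = NULL,
                            concepts = NULL, excluded_taxa = character()) {
  entries <- tibble::as_tibble(entries)
  need <- c("language", "concept", "cognate_class")
  if (!all(need %in% names(entries))) {
    stop("entries must have columns language, concept, cognate_class")
  }
  if (!"is_loan" %in% names(entries)) entries$is_loan <- FALSE
  entries <- entries[c("language", "concept", "cognate_class", "is_loan")]
  entries$language <- as.character(entries$language)
  entries$concept <- as.character(entries$concept)
  entries$cognate_class <- as.character(entries$cognate_class)
  entries$is_loan <- as.logical(entries$is_loan)
  if (anyNA(entries$language) || anyNA(entries$concept) ||
      anyNA(entries$cognate_class) || anyNA(entries$is_loan)) {
    stop("entries contain unparseable (NA) cells")
  }
  dup <- duplicated(entries[c("language", "concept", "cognate_class")])
  if (any(dup)) {
    stop("duplicate (language, concept, cognate_class) rows at: ",
         paste(which(dup), collapse = ", "))
  }
  languages <- languages %||% unique(entries$language)
  concepts <- concepts %||% unique(entries$concept)
  if (!all(entries$language %in% languages)) stop("entry language not in languages")
  if (!all(entries$concept %in% concepts)) stop("entry concept not in concepts")
  td <- tibble::tibble(language = languages, age_ka = 0)
  if (!is.null(tip_dates)) {
    if (is.numeric(tip_dates) && !is.null(names(tip_dates))) {
      tip_dates <- tibble::tibble(language = names(tip_dates), age_ka = unname(tip_dates))
    }
    tip_dates <- tibble::as_tibble(tip_dates)
    if (!all(tip_dates$language %in% languages)) {
      stop("tip date for unknown language: ",
           paste(setdiff(tip_dates$language, languages), collapse = ", "))
    }
    if (any(tip_dates$age_ka < 0)) stop("tip dates must be >= 0 ka BP")
    td$age_ka[match(tip_dates$language, td$language)] <- tip_dates$age_ka
  }
  structure(
    list(entries = entries, languages = languages, concepts = concepts,
         tip_dates = td, excluded_taxa = excluded_taxa),
    class = "cognate_dataset"
  )
}

#' @export
print.cognate_dataset <- function(x, ...) {
  cat("<cognate_dataset> ", length(x$languages), " languages x ",
      length(x$concepts), " concepts; ", nrow(x$entries), " entries (",
      sum(x$entries$is_loan), " loan-flagged); ",
      length(x$excluded_taxa), " excluded taxa\n", sep = "")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.cognate_dataset <- function(x, ...) x$entries

#' Read a multistate cognate table
#'
#' The CSV dialect is the full-fidelity interchange format: columns
#' `language, concept, cognate_class, is_loan`, one row per attested word.
#' NEXUS multistate input (one character per concept, one symbol per cognate
#' class) is read via [ape::read.nexus.data]; NEXUS carries no loan flags, so
#' all flags are `FALSE`, and tip dates must be supplied separately.
#'
#' @param path file to read.
#' @param format `"csv"` or `"nexus"`.
#' @param tip_dates passed to [cognate_dataset()].
#' @return a [cognate_dataset()].
#' @export
read_cognate_table <- function(path, format = c("csv", "nexus"),
                               tip_dates = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "csv") {
    entries <- readr::read_csv(path, col_types = readr::cols(
      language = readr::col_character(),
      concept = readr::col_character(),
      cognate_class = readr::col_character(),
      is_loan = readr::col_logical()
    ), progress = FALSE)
    prob <- readr::problems(entries)
    if (nrow(prob)) {
      stop("parse error in ", path, " at line ", prob$row[1], ": ",
           prob$expected[1], " vs ", prob$actual[1])
    }
    if (nrow(entries) == 0) stop("parse error: ", path, " has no data rows")
    cognate_dataset(entries, tip_dates = tip_dates)
  } else {
    nx <- ape::read.nexus.data(path)
    if (length(nx) == 0) stop("parse error: ", path, " has no taxa")
    ncha <- length(nx[[1]])
    concepts <- sprintf("c%03d", seq_len(ncha))
    rows <- purrr::map_dfr(names(nx), function(lang) {
      states <- nx[[lang]]
      purrr::map_dfr(seq_len(ncha), function(j) {
        syms <- setdiff(unique(strsplit(states[j], "")[[1]]), c("?", "-"))
        if (!length(syms)) return(NULL)
        tibble::tibble(language = lang, concept = concepts[j],
                       cognate_class = syms, is_loan = FALSE)
      })
    })
    cognate_dataset(rows, tip_dates = tip_dates,
                    languages = names(nx), concepts = concepts)
  }
}

#' Write a cognate dataset to the CSV dialect
#' @param ds a [cognate_dataset()].
#' @param path file to write.
#' @export
write_cognate_csv <- function(ds, path) {
  readr::write_csv(ds$entries, path, progress = FALSE)
  invisible(path)
}

#' Drop languages before analysis
#'
#' Removes the named languages (e.g. heavily borrowing or duplicated
#' varieties) and records them in `excluded_taxa`.
#'
#' @param ds a [cognate_dataset()].
#' @param names languages to drop; duplicates in the list are an error, to
#'   catch curation typos.
#' @return the reduced [cognate_dataset()].
#' @export
exclude_taxa <- function(ds, names) {
  if (anyDuplicated(names)) {
    stop("duplicate names in exclude list: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  unknown <- setdiff(names, ds$languages)
  if (length(unknown)) stop("unknown languages: ", paste(unknown, collapse = ", "))
  if (!length(names)) return(ds)
  keep <- setdiff(ds$languages, names)
  cognate_dataset(ds$entries[ds$entries$language %in% keep, ],
                  tip_dates = ds$tip_dates[ds$tip_dates$language %in% keep, ],
                  languages = keep, concepts = ds$concepts,
                  excluded_taxa = c(ds$excluded_taxa, names))
}

#' Remove loan-flagged cognates
#'
#' Deletes every loan-flagged class label. A (language, concept) pair whose
#' only labels were loans becomes a missing datum (`?` downstream), not an
#' absence: the native cognate is unknown, and coding 0 would assert loss.
#'
#' @param ds a [cognate_dataset()].
#' @return a loan-free [cognate_dataset()].
#' @export
remove_loans <- function(ds) {
  cognate_dataset(ds$entries[!ds$entries$is_loan, ],
                  tip_dates = ds$tip_dates, languages = ds$languages,
                  concepts = ds$concepts, excluded_taxa = ds$excluded_taxa)
}

#' Binary presence/absence matrices of cognate sets
#'
#' One column per (concept, cognate class) pair attested in at least one
#' language; a language scores 1 in the columns of classes it attests, 0 in
#' the other columns of concepts it attests, and `NA` (written `?`) in every
#' column of a concept it lacks.
#'
#' @param values integer matrix over `{0, 1, NA}`, rows named by language.
#' @param columns data frame with columns `concept`, `cognate_class`, one row
#'   per matrix column.
#' @return an object of class `binary_matrix`.
#' @export
binary_matrix <- function(values, columns) {
  columns <- tibble::as_tibble(columns)
  stopifnot(ncol(values) == nrow(columns),
            all(c("concept", "cognate_class") %in% names(columns)))
  if (is.null(rownames(values))) stop("values must have language rownames")
  storage.mode(values) <- "integer"
  ok <- is.na(values) | values == 0L | values == 1L
  if (!all(ok)) stop("binary matrix values must be 0, 1 or NA")
  structure(list(values = values, columns = columns,
                 languages = rownames(values),
                 n_cognate_sets = ncol(values)),
            class = "binary_matrix")
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat("<binary_matrix> ", length(x$languages), " languages x ",
      x$n_cognate_sets, " cognate sets (",
      length(unique(x$columns$concept)), " concepts)\n", sep = "")
  invisible(x)
}

#' Binarize a multistate cognate dataset
#'
#' Loans are removed internally before encoding. Column order is concepts in
#' dataset order, classes within a concept in first-attestation (entry row)
#' order, so output is deterministic.
#'
#' @param ds a [cognate_dataset()].
#' @return a [binary_matrix()].
#' @export
multistate_to_binary <- function(ds) {
  ds <- remove_loans(ds)
  e <- ds$entries
  if (nrow(e) == 0) stop("empty dataset: nothing to binarize")
  langs <- ds$languages
  cols <- dplyr::distinct(e[c("concept", "cognate_class")])
  cols <- cols[order(match(cols$concept, ds$concepts)), ]
  vals <- matrix(NA_integer_, length(langs), nrow(cols),
                 dimnames = list(langs, NULL))
  # a language attests a concept iff it has >= 1 (loan-free) entry for it
  attested <- dplyr::distinct(e[c("language", "concept")])
  for (j in seq_len(nrow(cols))) {
    has_concept <- attested$language[attested$concept == cols$concept[j]]
    vals[has_concept, j] <- 0L
  }
  ones <- match(paste(e$concept, e$cognate_class, sep = "\r"),
                paste(cols$concept, cols$cognate_class, sep = "\r"))
  vals[cbind(match(e$language, langs), ones)] <- 1L
  binary_matrix(vals, cols)
}

#' Compress a binary matrix to unique site patterns
#'
#' Identical columns are pooled with multiplicity weights; the likelihood of
#' the compressed patterns equals that of the full matrix.
#'
#' @param bm a [binary_matrix()].
#' @return an object of class `site_patterns` with fields `patterns`
#'   (languages x unique patterns, over `{0, 1, NA}`), `weights`, `n_sites`
#'   and `languages`.
#' @export
compress_patterns <- function(bm) {
  v <- bm$values
  key <- apply(v, 2, function(col) paste(ifelse(is.na(col), "?", col), collapse = ""))
  first <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[first])))
  structure(list(patterns = v[, first, drop = FALSE], weights = w,
                 n_sites = ncol(v), languages = rownames(v)),
            class = "site_patterns")
}

#' @export
print.site_patterns <- function(x, ...) {
  cat("<site_patterns> ", length(x$weights), " unique patterns over ",
      x$n_sites, " cognate sets, ", length(x$languages), " languages\n", sep = "")
  invisible(x)
}

#' Write / read a binary matrix as a NEXUS DATA block
#'
#' Standard datatype, symbols `"01"`, missing `?`; interoperable with other
#' NEXUS-aware phylogenetics tools. Reading uses [ape::read.nexus.data];
#' column (concept, class) labels are not part of the NEXUS format, so
#' re-read matrices carry generic column labels.
#'
#' @param bm a [binary_matrix()].
#' @param path file path.
#' @return `read_binary_nexus` returns a [binary_matrix()].
#' @export
write_binary_nexus <- function(bm, path) {
  nm <- gsub("[[:space:]]+", "_", bm$languages)
  seqs <- apply(bm$values, 1, function(r) paste(ifelse(is.na(r), "?", r), collapse = ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(nm), bm$n_cognate_sets),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
    "  MATRIX",
    sprintf("    %-*s %s", max(nchar(nm)), nm, seqs),
    "  ;",
    "END;"
  ), con)
  invisible(path)
}

#' @rdname write_binary_nexus
#' @export
read_binary_nexus <- function(path) {
  nx <- ape::read.nexus.data(path)
  vals <- do.call(rbind, lapply(nx, function(s) {
    v <- rep(NA_integer_, length(s))
    known <- s %in% c("0", "1")
    v[known] <- as.integer(s[known])
    v
  }))
  rownames(vals) <- names(nx)
  binary_matrix(vals, tibble::tibble(
    concept = sprintf("char%04d", seq_len(ncol(vals))),
    cognate_class = "1"
  ))
}
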