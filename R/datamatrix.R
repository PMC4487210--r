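#' @importFrom stats optimize runif rexp qgamma pgamma setNames
#' @importFrom utils head tail
NULL

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"), X = c("A", "C", "G", "T")
)

DNA_ALPHABET <- c("A", "C", "G", "T")

mask_from_states <- function(states, alphabet) {
  idx <- match(states, alphabet)
  if (anyNA(idx)) {
    stop("state(s) ", paste(states[is.na(idx)], collapse = ","),
         " not in alphabet {", paste(alphabet, collapse = ""), "}")
  }
  sum(bitwShiftL(1L, idx - 1L))
}

states_from_mask <- function(mask, alphabet) {
  alphabet[bitwAnd(bitwShiftR(mask, seq_along(alphabet) - 1L), 1L) == 1L]
}

full_mask <- function(k) bitwShiftL(1L, k) - 1L

#' Taxa-by-characters state-set matrix
#'
#' The central data container: a table of taxa (rows) by characters
#' (columns) whose cells are *sets* of states. Categorical morphology uses
#' arbitrary single-character symbols with polymorphic cells written
#' `{ab}`; nucleotide data uses `A`,`C`,`G`,`T` with IUPAC ambiguity codes
#' expanding to state sets. Missing cells (`?`, and by default the gap
#' `-`) are recorded as missing and enter parsimony/likelihood as the full
#' state set, but are excluded from pairwise distances.
#'
#' @param x a character matrix of cell tokens (rows = taxa, must have
#'   rownames), or a named character vector giving each taxon's row as a
#'   single string, e.g. `c(A = "011", B = "0{12}?")`.
#' @param type `"categorical"` or `"nucleotide"`.
#' @param symbols state symbols for categorical data; defaults to the
#'   symbols observed. Ignored for nucleotide data.
#' @param missing_char,gap_char single characters marking missing data and
#'   gaps.
#' @param gap_as_state treat the gap as an extra state rather than as
#'   missing (categorical data only).
#' @param weights per-character weights (default 1).
#' @return an object of class `data_matrix`.
#' @export
data_matrix <- function(x, type = c("categorical", "nucleotide"),
                        symbols = NULL, missing_char = "?", gap_char = "-",
                        gap_as_state = FALSE, weights = NULL) {
  type <- match.arg(type)
  if (is.character(x) && is.null(dim(x))) {
    if (is.null(names(x))) stop("row strings must be named by taxon")
    rows <- lapply(x, tokenize_cells, where = "row")
    nc <- lengths(rows)
    if (length(unique(nc)) != 1L)
      stop("rows have unequal numbers of cells: ", paste(nc, collapse = ","))
    x <- matrix(unlist(rows), nrow = length(rows), byrow = TRUE,
                dimnames = list(names(x), NULL))
  }
  if (is.null(rownames(x))) stop("taxon labels (rownames) required")
  taxa <- rownames(x)
  if (anyDuplicated(taxa)) stop("duplicate taxon label: ",
                                taxa[duplicated(taxa)][1L])
  n <- nrow(x); m <- ncol(x)
  if (type == "nucleotide") {
    alphabet_master <- DNA_ALPHABET
  } else {
    if (is.null(symbols)) {
      toks <- setdiff(unique(unlist(strsplit(x, ""))),
                      c("{", "}", "(", ")", missing_char, gap_char, " "))
      symbols <- sort(toks)
    }
    if (gap_as_state) symbols <- unique(c(symbols, gap_char))
    alphabet_master <- symbols
  }
  k <- length(alphabet_master)
  masks <- matrix(0L, n, m, dimnames = list(taxa, colnames(x)))
  miss <- matrix(FALSE, n, m, dimnames = list(taxa, colnames(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      tok <- x[i, j]
      res <- cell_mask(tok, type, alphabet_master, missing_char, gap_char,
                       gap_as_state)
      if (is.null(res))
        stop("symbol '", tok, "' outside declared symbols at taxon '",
             taxa[i], "', character ", j)
      masks[i, j] <- res$mask
      miss[i, j] <- res$miss
    }
  }
  if (is.null(weights)) weights <- rep(1, m)
  stopifnot(length(weights) == m, all(weights >= 0))
  structure(list(taxa = taxa, type = type, alphabet = alphabet_master,
                 masks = masks, miss = miss, weights = as.numeric(weights)),
            class = "data_matrix")
}

# split a row string like "0{12}?A" into cell tokens
tokenize_cells <- function(s, where = "") {
  chars <- strsplit(s, "")[[1]]
  out <- character(0); i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- i + 1L
      while (j <= length(chars) && chars[j] != close) j <- j + 1L
      if (j > length(chars)) stop("unclosed '", ch, "' in ", where, " '", s, "'")
      out <- c(out, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

cell_mask <- function(tok, type, alphabet, missing_char, gap_char,
                      gap_as_state = FALSE) {
  k <- length(alphabet)
  if (tok == missing_char) return(list(mask = full_mask(k), miss = TRUE))
  if (tok == gap_char && !gap_as_state)
    return(list(mask = full_mask(k), miss = TRUE))
  states <- if (grepl("^[{(]", tok)) {
    strsplit(gsub("[{}()]", "", tok), "")[[1]]
  } else tok
  if (type == "nucleotide") {
    states <- unique(unlist(IUPAC_SETS[toupper(states)]))
    if (length(states) == 0) return(NULL)
    if (setequal(states, alphabet) && toupper(tok) %in% c("N", "X"))
      return(list(mask = full_mask(k), miss = FALSE))
  }
  if (!all(states %in% alphabet)) return(NULL)
  list(mask = mask_from_states(states, alphabet), miss = FALSE)
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("data_matrix: %d taxa x %d characters (%s)\n",
              length(x$taxa), ncol(x$masks), x$type))
  cat("  symbols: ", paste(x$alphabet, collapse = ""), "\n", sep = "")
  cat("  missing cells: ", sum(x$miss), "\n", sep = "")
  invisible(x)
}

#' @export
dim.data_matrix <- function(x) dim(x$masks)

#' Number of taxa / characters
#' @param m a `data_matrix`.
#' @export
n_taxa <- function(m) length(m$taxa)

#' @rdname n_taxa
#' @export
n_char <- function(m) ncol(m$masks)

#' @export
`[.data_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$taxa)
  if (missing(j)) j <- seq_len(ncol(x$masks))
  if (is.character(i)) i <- match(i, x$taxa)
  structure(list(taxa = x$taxa[i], type = x$type, alphabet = x$alphabet,
                 masks = x$masks[i, j, drop = FALSE],
                 miss = x$miss[i, j, drop = FALSE],
                 weights = x$weights[j]),
            class = "data_matrix")
}

#' Cell state sets as a list matrix
#'
#' Expands the packed representation back into explicit per-cell state
#' sets; missing cells are `NA`.
#' @param m a `data_matrix`.
#' @return a list matrix of character vectors.
#' @export
matrix_states <- function(m) {
  out <- matrix(vector("list", length(m$masks)), nrow(m$masks), ncol(m$masks),
                dimnames = dimnames(m$masks))
  for (i in seq_len(nrow(m$masks)))
    for (j in seq_len(ncol(m$masks)))
      out[[i, j]] <- if (m$miss[i, j]) NA_character_ else
        states_from_mask(m$masks[i, j], m$alphabet)
  out
}

#' Bind rows of two compatible data matrices
#'
#' Used to append a query (e.g. fossil) row to a backbone matrix. Both
#' matrices must share type, alphabet and character count.
#' @param a,b `data_matrix` objects.
#' @return a `data_matrix` with the rows of `a` then `b`.
#' @export
bind_taxa <- function(a, b) {
  stopifnot(a$type == b$type, identical(a$alphabet, b$alphabet),
            ncol(a$masks) == ncol(b$masks))
  if (any(b$taxa %in% a$taxa))
    stop("duplicate taxon label: ", intersect(a$taxa, b$taxa)[1L])
  structure(list(taxa = c(a$taxa, b$taxa), type = a$type,
                 alphabet = a$alphabet,
                 masks = rbind(a$masks, b$masks),
                 miss = rbind(a$miss, b$miss), weights = a$weights),
            class = "data_matrix")
}

#' Mean inter-taxon character distance matrix
#'
#' For each pair of taxa, the proportion of characters scored in both
#' whose state sets are disjoint (overlap of polymorphic sets counts as a
#' match). Missing cells are dropped pairwise, which keeps sparse fossil
#' rows usable. Pairs with no comparable characters get `NA` ("undefined")
#' rather than an imputed value.
#'
#' @param m a `data_matrix`.
#' @return a `dist_matrix`: list with `labels`, symmetric matrix `d` in
#'   \[0,1\] (NA where undefined), and `ncomp`, the per-pair count of
#'   comparable characters.
#' @export
mean_distance_matrix <- function(m) {
  n <- n_taxa(m)
  if (n < 2) stop("need at least 2 taxa")
  scored <- !m$miss
  if (any(rowSums(scored) == 0))
    warning("taxa with no scored characters: ",
            paste(m$taxa[rowSums(scored) == 0], collapse = ", "))
  d <- matrix(0, n, n, dimnames = list(m$taxa, m$taxa))
  ncomp <- matrix(0L, n, n, dimnames = list(m$taxa, m$taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- scored[i, ] & scored[j, ]
      nc <- sum(comp)
      ncomp[i, j] <- ncomp[j, i] <- nc
      if (nc == 0) { d[i, j] <- d[j, i] <- NA_real_; next }
      mismatch <- bitwAnd(m$masks[i, comp], m$masks[j, comp]) == 0L
      d[i, j] <- d[j, i] <- sum(mismatch) / nc
    }
  }
  structure(list(labels = m$taxa, d = d, ncomp = ncomp),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix over %d taxa", length(x$labels)))
  und <- sum(is.na(x$d[upper.tri(x$d)]))
  if (und > 0) cat(sprintf(" (%d undefined pairs)", und))
  cat("\n")
  invisible(x)
}

#' Collapse identical columns into patterns
#'
#' Two columns share a pattern iff their full taxon-state vectors are
#' identical (state sets and missingness both compared).
#' @param m a `data_matrix`.
#' @return list with `index` (column -> pattern id), `counts`
#'   (multiplicity per pattern), `n_patterns`, and `representatives`
#'   (first column of each pattern).
#' @export
compress_patterns <- function(m) {
  key <- apply(rbind(m$masks, m$miss), 2, paste, collapse = "|")
  ids <- match(key, unique(key))
  counts <- tabulate(ids)
  list(index = ids, counts = counts, n_patterns = length(counts),
       representatives = match(seq_along(counts), ids))
}

#' Share of distinct alignment patterns carried by a partition subset
#'
#' Percentage of the concatenated matrix's distinct column patterns that
#' occur among the columns of the named partitions.
#' @param m a `data_matrix`.
#' @param scheme a `partition_scheme`.
#' @param subset character vector of partition names.
#' @return a percentage in \[0, 100\].
#' @export
pattern_share <- function(m, scheme, subset) {
  stopifnot(inherits(scheme, "partition_scheme"))
  if (length(subset) == 0) return(0)
  bad <- setdiff(subset, names(scheme$cols))
  if (length(bad)) stop("unknown partition(s): ", paste(bad, collapse = ", "))
  cp <- compress_patterns(m)
  cols <- sort(unique(unlist(scheme$cols[subset])))
  100 * length(unique(cp$index[cols])) / cp$n_patterns
}

#' Partition scheme over alignment columns
#'
#' @param cols named list of integer column-index vectors (1-based),
#'   pairwise disjoint.
#' @param flags optional named character vector of partition roles, e.g.
#'   `c(rbcL = "coding", trnLF = "spacer")`.
#' @return an object of class `partition_scheme`.
#' @export
partition_scheme <- function(cols, flags = NULL) {
  stopifnot(is.list(cols), !is.null(names(cols)), all(nzchar(names(cols))))
  all_cols <- unlist(cols)
  if (anyDuplicated(all_cols))
    stop("partitions overlap at column(s) ",
         paste(head(unique(all_cols[duplicated(all_cols)]), 5), collapse = ","))
  if (is.null(flags)) flags <- setNames(rep(NA_character_, length(cols)),
                                        names(cols))
  structure(list(cols = lapply(cols, as.integer), flags = flags),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat("partition_scheme:\n")
  for (nm in names(x$cols))
    cat(sprintf("  %s: %d columns%s\n", nm, length(x$cols[[nm]]),
                if (!is.na(x$flags[[nm]])) paste0(" [", x$flags[[nm]], "]") else ""))
  invisible(x)
}
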