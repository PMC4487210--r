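# Readers and writers for the external formats the workflow touches:
# NEXUS character blocks (multistate symbols, polymorphism, interleaving),
# relaxed PHYLIP and FASTA alignments, RAxML-style partition files, newick
# tree lists and splits-NEXUS blocks for splits-graph viewers. All pairs
# round-trip losslessly; parsers fail with located errors rather than
# truncating silently.

read_text <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    return(readLines(x, warn = FALSE))
  unlist(strsplit(x, "\n"))
}

strip_nexus_comments <- function(lines) gsub("\\[[^]]*\\]", "", lines)

#' Read a NEXUS character matrix
#'
#' Parses DATA/CHARACTERS blocks with multistate symbols, missing `?`,
#' gap `-`, polymorphic `{..}`/`(..)` cells, quoted or underscored taxon
#' labels, and interleaved matrices. Errors name the offending line,
#' taxon or cell.
#'
#' @param x path to a file or NEXUS text.
#' @param gap_as_state treat gaps as an extra state instead of missing.
#' @return a [data_matrix()].
#' @export
read_nexus_characters <- function(x, gap_as_state = FALSE) {
  lines <- strip_nexus_comments(read_text(x))
  txt <- paste(lines, collapse = "\n")
  if (!grepl("#NEXUS", txt, ignore.case = TRUE))
    stop("not a NEXUS file (missing #NEXUS header)")
  grab <- function(pattern) {
    mm <- regmatches(txt, regexpr(pattern, txt, ignore.case = TRUE, perl = TRUE))
    if (length(mm) == 0) NA_character_ else mm
  }
  dims <- grab("DIMENSIONS[^;]*;")
  if (is.na(dims)) stop("missing DIMENSIONS statement")
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*(\\d+).*", "\\1", dims, ignore.case = TRUE))
  nchr <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1", dims, ignore.case = TRUE))
  if (is.na(ntax) || is.na(nchr)) stop("DIMENSIONS must give NTAX and NCHAR")
  fmt <- grab("FORMAT[^;]*;")
  datatype <- "standard"; symbols <- NULL; missing_char <- "?"; gap_char <- "-"
  interleave <- FALSE
  if (!is.na(fmt)) {
    if (grepl("DATATYPE\\s*=\\s*DNA", fmt, ignore.case = TRUE)) datatype <- "dna"
    sm <- regmatches(fmt, regexpr('SYMBOLS\\s*=\\s*"[^"]*"', fmt, ignore.case = TRUE))
    if (length(sm)) {
      symbols <- strsplit(gsub('.*"([^"]*)".*', "\\1", sm), "")[[1]]
      symbols <- symbols[symbols != " "]
    }
    mc <- regmatches(fmt, regexpr("MISSING\\s*=\\s*\\S", fmt, ignore.case = TRUE))
    if (length(mc)) missing_char <- substring(mc, nchar(mc))
    gc <- regmatches(fmt, regexpr("GAP\\s*=\\s*\\S", fmt, ignore.case = TRUE))
    if (length(gc)) gap_char <- substring(gc, nchar(gc))
    interleave <- grepl("INTERLEAV", fmt, ignore.case = TRUE)
  }
  # matrix section: from the MATRIX keyword to the closing ';'
  mstart <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)
  if (length(mstart) == 0)
    mstart <- grep("^\\s*MATRIX", lines, ignore.case = TRUE)
  if (length(mstart) == 0) stop("missing MATRIX section")
  body <- lines[(mstart[1] + 1):length(lines)]
  endrow <- grep("^\\s*;", body)
  semi_inline <- grep(";\\s*$", body)
  stop_at <- min(c(endrow, semi_inline, length(body) + 1L))
  body <- body[seq_len(min(stop_at, length(body)))]
  body <- sub(";\\s*$", "", body)
  body <- body[nzchar(trimws(body))]
  rows <- list()
  for (li in seq_along(body)) {
    ln <- trimws(body[li])
    if (grepl("^'", ln)) {
      close_q <- regexpr("'", substring(ln, 2), fixed = TRUE)
      if (close_q < 0) stop("unterminated quoted label at matrix line ", li)
      label <- substr(ln, 2, close_q)
      rest <- trimws(substring(ln, close_q + 2))
    } else {
      label <- sub("\\s.*$", "", ln)
      rest <- trimws(sub("^\\S+\\s*", "", ln))
    }
    rest <- gsub("\\s", "", rest)
    if (!nzchar(label)) stop("empty taxon label at matrix line ", li)
    if (!is.null(rows[[label]]) && !interleave)
      stop("duplicate taxon label '", label, "' at matrix line ", li)
    rows[[label]] <- paste0(if (is.null(rows[[label]])) "" else rows[[label]], rest)
  }
  if (length(rows) != ntax)
    stop("DIMENSIONS declares NTAX=", ntax, " but matrix has ",
         length(rows), " taxa")
  cells <- lapply(rows, tokenize_cells, where = "matrix row")
  nc <- lengths(cells)
  if (any(nc != nchr))
    stop("taxon '", names(rows)[which(nc != nchr)[1]], "' has ",
         nc[which(nc != nchr)[1]], " characters, expected NCHAR=", nchr)
  xmat <- matrix(unlist(cells), nrow = length(rows), byrow = TRUE,
                 dimnames = list(names(rows), NULL))
  data_matrix(xmat, type = if (datatype == "dna") "nucleotide" else "categorical",
              symbols = symbols, missing_char = missing_char,
              gap_char = gap_char, gap_as_state = gap_as_state)
}

cell_token <- function(mask, miss, alphabet, missing_char = "?") {
  if (miss) return(missing_char)
  st <- states_from_mask(mask, alphabet)
  if (length(st) == 1) return(st)
  if (length(alphabet) == 4 && all(alphabet == DNA_ALPHABET)) {
    key <- paste(sort(st), collapse = "")
    for (nm in names(IUPAC_SETS)) {
      if (nm %in% c("U", "X")) next
      if (paste(sort(IUPAC_SETS[[nm]]), collapse = "") == key) return(nm)
    }
  }
  paste0("{", paste(st, collapse = ""), "}")
}

row_string <- function(m, i, missing_char = "?") {
  paste(vapply(seq_len(ncol(m$masks)), function(j)
    cell_token(m$masks[i, j], m$miss[i, j], m$alphabet, missing_char), ""),
    collapse = "")
}

quote_label <- function(x) {
  ifelse(grepl("[][ '(){};,]", x), paste0("'", gsub("'", "''", x), "'"), x)
}

#' Write a NEXUS character matrix
#' @param m a [data_matrix()].
#' @param file output path (or `""` to return the text invisibly).
#' @return the NEXUS text, invisibly.
#' @export
write_nexus_characters <- function(m, file = "") {
  dna <- m$type == "nucleotide"
  fmt <- if (dna) "    FORMAT DATATYPE=DNA MISSING=? GAP=-;" else
    sprintf('    FORMAT DATATYPE=STANDARD SYMBOLS="%s" MISSING=? GAP=-;',
            paste(m$alphabet, collapse = ""))
  lab <- quote_label(m$taxa)
  pad <- max(nchar(lab)) + 2
  out <- c("#NEXUS", "BEGIN CHARACTERS;",
           sprintf("    DIMENSIONS NTAX=%d NCHAR=%d;", n_taxa(m), n_char(m)),
           fmt, "    MATRIX",
           vapply(seq_len(n_taxa(m)), function(i)
             sprintf("    %-*s%s", pad, lab[i], row_string(m, i)), ""),
           "    ;", "END;")
  txt <- paste(out, collapse = "\n")
  if (nzchar(file)) writeLines(txt, file)
  invisible(txt)
}

#' Read a nucleotide alignment (relaxed PHYLIP or FASTA)
#'
#' IUPAC ambiguity codes become state sets; `-` and `?` are missing.
#' @param x path or text.
#' @param format `"auto"` sniffs FASTA (`>` header) vs PHYLIP.
#' @return a [data_matrix()] of type `"nucleotide"`.
#' @export
read_alignment <- function(x, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  lines <- read_text(x)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "auto")
    format <- if (grepl("^>", trimws(lines[1]))) "fasta" else "phylip"
  if (format == "fasta") {
    hdr <- grep("^>", lines)
    if (length(hdr) == 0) stop("no FASTA headers found")
    labels <- sub("^>\\s*", "", lines[hdr])
    seqs <- vapply(seq_along(hdr), function(i) {
      from <- hdr[i] + 1
      to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(lines)
      if (from > to) stop("empty sequence for '", labels[i], "'")
      gsub("\\s", "", paste(lines[from:to], collapse = ""))
    }, "")
    if (length(unique(nchar(seqs))) != 1)
      stop("sequences have unequal lengths: ",
           paste(unique(nchar(seqs)), collapse = ","))
  } else {
    hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(hdr) < 2 || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
      stop("PHYLIP header must be '<ntax> <nchar>' (line 1)")
    ntax <- as.integer(hdr[1]); nchr <- as.integer(hdr[2])
    labels <- character(0); seqs <- character(0)
    i <- 2L; cur <- 0L
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (cur == 0L || nchar(seqs[cur]) >= nchr) {
        labels <- c(labels, sub("\\s.*$", "", ln))
        seqs <- c(seqs, gsub("\\s", "", sub("^\\S+\\s*", "", ln)))
        cur <- cur + 1L
      } else {
        seqs[cur] <- paste0(seqs[cur], gsub("\\s", "", ln))
      }
      i <- i + 1L
    }
    if (length(labels) != ntax)
      stop("header declares ", ntax, " taxa but found ", length(labels))
    bad <- which(nchar(seqs) != nchr)
    if (length(bad))
      stop("sequence length mismatch for '", labels[bad[1]], "': ",
           nchar(seqs[bad[1]]), " vs declared ", nchr)
  }
  if (anyDuplicated(labels))
    stop("duplicate taxon label: ", labels[duplicated(labels)][1])
  data_matrix(setNames(toupper(seqs), labels), type = "nucleotide")
}

#' Write a nucleotide alignment
#' @param m a [data_matrix()].
#' @param file output path (or `""`).
#' @param format `"phylip"` or `"fasta"`.
#' @return the text, invisibly.
#' @export
write_alignment <- function(m, file = "", format = c("phylip", "fasta")) {
  format <- match.arg(format)
  seqs <- vapply(seq_len(n_taxa(m)), function(i) row_string(m, i), "")
  txt <- if (format == "phylip") {
    paste(c(sprintf("%d %d", n_taxa(m), n_char(m)),
            sprintf("%s  %s", m$taxa, seqs)), collapse = "\n")
  } else {
    paste(rbind(paste0(">", m$taxa), seqs), collapse = "\n")
  }
  if (nzchar(file)) writeLines(txt, file)
  invisible(txt)
}

#' Read a RAxML-style partition file
#'
#' Lines like `DNA, rbcL = 1-1206` or `p3 = 1-12\3, 30-40`; ranges are
#' 1-based inclusive, `\\k` takes every k-th column. Overlapping
#' partitions are an error.
#' @param x path or text.
#' @param flags optional named character vector of partition roles.
#' @return a [partition_scheme()].
#' @export
read_partition_scheme <- function(x, flags = NULL) {
  lines <- read_text(x)
  lines <- lines[nzchar(trimws(lines))]
  cols <- list()
  for (li in seq_along(lines)) {
    ln <- trimws(lines[li])
    if (!grepl("=", ln)) stop("line ", li, ": expected 'name = ranges'")
    lhs <- trimws(sub("=.*$", "", ln))
    name <- trimws(tail(strsplit(lhs, ",")[[1]], 1))
    rhs <- trimws(sub("^[^=]*=", "", ln))
    pieces <- trimws(strsplit(rhs, ",")[[1]])
    idx <- integer(0)
    for (p in pieces) {
      mm <- regmatches(p, regexec("^(\\d+)(?:\\s*-\\s*(\\d+))?(?:\\\\(\\d+))?$", p))[[1]]
      if (length(mm) == 0) stop("line ", li, ": cannot parse range '", p, "'")
      from <- as.integer(mm[2])
      to <- if (nzchar(mm[3])) as.integer(mm[3]) else from
      by <- if (nzchar(mm[4])) as.integer(mm[4]) else 1L
      if (to < from) stop("line ", li, ": empty range '", p, "'")
      idx <- c(idx, seq(from, to, by = by))
    }
    if (!is.null(cols[[name]])) stop("line ", li, ": duplicate partition '", name, "'")
    cols[[name]] <- idx
  }
  partition_scheme(cols, flags = flags)
}

#' Read / write newick tree files
#'
#' Thin wrappers over ape's newick machinery. `read_trees` drops `[...]`
#' comments, accepts quoted labels, and tags each tree with whether its
#' basal node is a bifurcation (rooted) or a multifurcation (unrooted).
#' `write_trees` keeps branch lengths to 12 significant digits.
#' @param x path or newick text (one or more trees).
#' @return a `multiPhylo` with a logical `rooted` attribute.
#' @export
read_trees <- function(x) {
  txt <- paste(read_text(x), collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt)
  # turn quoted labels into plain ones ape can digest (spaces -> _)
  txt <- vapply(txt, function(s) s, "")
  m <- gregexpr("'[^']*'", txt)
  regmatches(txt, m) <- lapply(regmatches(txt, m), function(labs)
    gsub(" ", "_", gsub("'", "", labs)))
  txt <- unname(txt)
  trees <- ape::read.tree(text = txt)
  if (is.null(trees)) stop("no parseable newick tree found")
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  attr(trees, "rooted") <- vapply(trees, ape::is.rooted, logical(1))
  trees
}

#' @rdname read_trees
#' @param trees a `phylo` or `multiPhylo`.
#' @param file output path (or `""`).
#' @export
write_trees <- function(trees, file = "") {
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  txt <- paste(vapply(trees, function(tr)
    ape::write.tree(tr, digits = 12), ""), collapse = "\n")
  if (nzchar(file)) writeLines(txt, file)
  invisible(txt)
}

#' Export / import a split system as splits-NEXUS
#'
#' Emits the st_splits block used by splits-graph viewers (weights, and
#' the circular ordering as a CYCLE statement when present).
#' @param ss a `split_system`.
#' @param file output path (or `""`).
#' @return the NEXUS text, invisibly.
#' @export
write_splits_nexus <- function(ss, file = "") {
  n <- length(ss$labels)
  lab <- quote_label(ss$labels)
  lines <- c("#NEXUS", "BEGIN Taxa;",
             sprintf("DIMENSIONS ntax=%d;", n),
             "TAXLABELS",
             sprintf("[%d] %s", seq_len(n), lab),
             ";", "END;", "BEGIN Splits;",
             sprintf("DIMENSIONS ntax=%d nsplits=%d;", n, length(ss$weights)),
             "FORMAT labels=no weights=yes confidences=no intervals=no;")
  if (!is.null(ss$ordering)) {
    ord_idx <- match(ss$ordering, ss$labels)
    lines <- c(lines, "PROPERTIES fit=-1.0 cyclic;",
               paste("CYCLE", paste(ord_idx, collapse = " "), ";"))
  }
  lines <- c(lines, "MATRIX")
  for (i in seq_along(ss$weights)) {
    side <- ss$sides[[i]]
    lines <- c(lines, sprintf("[%d, size=%d] \t%.12g \t %s,", i, length(side),
                              ss$weights[i], paste(side, collapse = " ")))
  }
  lines <- c(lines, ";", "END;")
  txt <- paste(lines, collapse = "\n")
  if (nzchar(file)) writeLines(txt, file)
  invisible(txt)
}

#' @rdname write_splits_nexus
#' @param x path or splits-NEXUS text.
#' @export
read_splits_nexus <- function(x) {
  lines <- read_text(x)
  txt <- paste(lines, collapse = "\n")
  tax_m <- regmatches(txt, regexpr("TAXLABELS.*?;", txt, ignore.case = TRUE))
  if (length(tax_m) == 0) stop("missing TAXLABELS")
  toks <- strsplit(gsub("\\[\\d+\\]|TAXLABELS|;", "", tax_m), "\\s+")[[1]]
  labels <- gsub("'", "", toks[nzchar(toks)])
  cyc <- regmatches(txt, regexpr("CYCLE[^;]*;", txt, ignore.case = TRUE))
  ordering <- NULL
  if (length(cyc))
    ordering <- labels[as.integer(strsplit(trimws(gsub("CYCLE|;", "", cyc)), "\\s+")[[1]])]
  mstart <- grep("^\\s*MATRIX", lines, ignore.case = TRUE)
  splits_at <- grep("BEGIN\\s+Splits", lines, ignore.case = TRUE)
  mstart <- mstart[mstart > splits_at[1]][1]
  sides <- list(); weights <- numeric(0)
  for (ln in lines[(mstart + 1):length(lines)]) {
    ln <- trimws(ln)
    if (grepl("^;", ln) || grepl("^END", ln, ignore.case = TRUE)) break
    if (!nzchar(ln)) next
    ln <- gsub("\\[[^]]*\\]", "", ln)
    ln <- sub(",\\s*$", "", ln)
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    weights <- c(weights, as.numeric(toks[1]))
    sides <- c(sides, list(as.integer(toks[-1])))
  }
  split_system(labels, sides, weights, ordering = ordering)
}
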