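# Shared fixtures, built in code.

# distance matrix container from a plain symmetric matrix
dm_fix <- function(M, labels = rownames(M)) {
  dimnames(M) <- list(labels, labels)
  structure(list(labels = labels, d = M, ncomp = NULL),
            class = "dist_matrix")
}

# equality of two data matrices at the state-set level
expect_same_matrix <- function(a, b) {
  expect_identical(a$taxa, b$taxa)
  expect_identical(a$alphabet, b$alphabet)
  expect_true(all(a$masks == b$masks))
  expect_true(all(a$miss == b$miss))
}

# a small quartet tree with a strong internal branch
quartet_tree <- function() {
  ape::read.tree(text = "((A:0.1,B:0.1):0.5,(C:0.1,D:0.1):0.0);")
}

# canonical split keys of a split system
ss_keys <- function(ss) {
  vapply(ss$sides, function(s) split_key(ss$labels[s], ss$labels), "")
}

# non-interleaved / interleaved encodings of one 4 x 6 matrix
nexus_plain <- function() {
  paste0("#NEXUS\nBEGIN DATA;\nDIMENSIONS NTAX=4 NCHAR=6;\n",
         "FORMAT DATATYPE=STANDARD SYMBOLS=\"012\" MISSING=? GAP=-;\n",
         "MATRIX\nta 012012\ntb 0?2{01}12\ntc 000000\ntd 211102\n;\nEND;")
}

nexus_interleaved <- function() {
  paste0("#NEXUS\nBEGIN DATA;\nDIMENSIONS NTAX=4 NCHAR=6;\n",
         "FORMAT DATATYPE=STANDARD SYMBOLS=\"012\" MISSING=? GAP=- ",
         "INTERLEAVE;\nMATRIX\nta 012\ntb 0?2\ntc 000\ntd 211\n",
         "ta 012\ntb {01}12\ntc 000\ntd 102\n;\nEND;")
}
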