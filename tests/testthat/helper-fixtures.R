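# shared fixtures, built in code

# the bundled 38-row gene table (37 genes + CR, 16,571 bp)
table_annotation <- function() {
  read_feature_table(crepasson_feature_table(), genome_id = "PP937077")
}

# one default synthetic ancestor per session (generation is deterministic)
local({
  cache <- new.env(parent = emptyenv())
  ancestor_fixture <<- function(seed = 101L) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) cache[[key]] <- make_ancestor(sim_config(seed = seed))
    cache[[key]]
  }
})

# minimal GenBank flat-file text for a small annotated genome
genbank_text <- function(seq, feats, id = "TEST0001") {
  loc <- function(f) {
    base <- paste0(f$start, "..", f$end)
    if (f$strand == "L") paste0("complement(", base, ")") else base
  }
  key <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", CR = "D-loop")
  flines <- unlist(lapply(seq_len(nrow(feats)), function(i) {
    f <- feats[i, ]
    c(
      sprintf("     %-16s%s", key[[f$cls]], loc(f)),
      if (f$cls != "CR") sprintf("                     /gene=\"%s\"", f$gene)
    )
  }))
  olines <- vapply(seq(1L, nchar(seq), by = 60L), function(p) {
    chunk <- substr(seq, p, min(p + 59L, nchar(seq)))
    grp <- gsub("(.{10})", "\\1 ", chunk)
    sprintf("%9d %s", p, tolower(grp))
  }, character(1))
  c(
    sprintf("LOCUS       %s %d bp DNA circular VRT", id, nchar(seq)),
    sprintf("ACCESSION   %s", id),
    "FEATURES             Location/Qualifiers",
    flines,
    "ORIGIN",
    olines,
    "//"
  )
}

random_dna <- function(n, seed = NULL, freq = rep(0.25, 4)) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freq),
        collapse = "")
}
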