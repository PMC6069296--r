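# Alignment fixtures built in code.

# A block alignment whose splits are each backed by `block` private columns:
# every bootstrap resample retains all splits, so supports are 100.
# Unrooted shape: ((A,B),(C,D),(E,F)); F serves as outgroup.
clean_six_taxon_alignment <- function(block = 40L) {
  taxa <- c("A", "B", "C", "D", "E", "F")
  L <- 4L * block
  m <- matrix("A", length(taxa), L, dimnames = list(taxa, NULL))
  cols <- function(i) ((i - 1L) * block + 1L):(i * block)
  m[c("A", "B"), cols(1L)] <- "C"            # split AB | CDEF
  m[c("C", "D"), cols(2L)] <- "G"            # split CD | ABEF
  m[c("A", "B", "C", "D"), cols(3L)] <- "T"  # split ABCD | EF
  # block 4 stays constant
  m
}

# Quartet alignment for a chosen topology: private columns on the internal
# branch plus tip-private columns (which do not carry split information).
quartet_alignment <- function(pair1, pair2, internal = 30L, tip = 10L) {
  taxa <- sort(c(pair1, pair2))
  L <- internal + 4L * tip
  m <- matrix("A", 4L, L, dimnames = list(taxa, NULL))
  m[pair1, seq_len(internal)] <- "G"
  for (i in seq_len(4L)) {
    m[taxa[i], internal + ((i - 1L) * tip + 1L):(i * tip)] <- "T"
  }
  m
}

# Split a matrix into per-gene chunks and write them as a FASTA directory.
write_fasta_dir <- function(genes, dir = withr::local_tempdir(.local_envir =
                                                              parent.frame())) {
  for (g in names(genes)) {
    m <- genes[[g]]
    lines <- as.vector(rbind(paste0(">", rownames(m)),
                             apply(m, 1L, paste, collapse = "")))
    writeLines(lines, file.path(dir, paste0(g, ".fasta")))
  }
  dir
}

# Minimal fake records for history-level functions (report, frequencies).
fake_record <- function(topology, score = 90, p = 90, b = 90,
                        word = "1111", ordinal = 1L) {
  list(word = word, bits = word_from_string(word), b = b, p = p,
       score = score, topology = topology,
       supports = c(stats::setNames(b, "cl")), tree = NULL,
       well_supported = b > 95, ordinal = ordinal)
}

fake_history <- function(topologies) {
  structure(lapply(seq_along(topologies), function(i) {
    fake_record(topologies[[i]], ordinal = i)
  }), class = "run_history")
}
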