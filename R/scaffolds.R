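# Fixed VHH framework scaffolds used by the repertoire simulator.
#
# Segment lengths are chosen so that a full amplicon (forward primer +
# coding insert + reverse-primer site) stays short enough for 2 x 300 bp
# read pairs to overlap comfortably, while every simulated VHH keeps the
# canonical CDR3 anchors: the FR3 terminal "...YYC" cysteine and the FR4
# "WGQG" tryptophan.

.FR1B <- c("GGLVQAGGSLRLSAAAS", "GGLVQPGGSLRLSAVAS")        # 17 aa
.FR2  <- c("MGWFRQAPGKEREF", "MAWFRQAPGKGREF")               # 14 aa
.FR3  <- c("DSVKGRFTISRDNAKNTVYLQMNSLKPEDTAVYYC",           # 35 aa, ends YYC
           "DSVKGRFTISRDNSKNTLYLQMNSLKPEDTAVYYC")
.FR4  <- "WGQGTQVTVSS"                                       # 11 aa, starts WGQG
.HINGE <- c(short_IgG2 = "AHHSEDPS",                         # 8 aa
            long_IgG3 = "EPKTPKPQPNPT")                      # 12 aa

# CDR alphabets exclude Cys and Trp so the single FR3 Cys / FR4 Trp stay
# unambiguous anchors for extraction.
.CDR_ALPHABET <- setdiff(strsplit("ARNDQEGHILKMFPSTYV", "")[[1]], c("C", "W"))

# codon table for randomized reverse translation
.CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

# reverse-translate an amino-acid string with random synonymous codons
# (consumes the current RNG stream)
.reverseTranslate <- function(aa) {
  ch <- strsplit(aa, "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(a) {
    cods <- .CODONS[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}
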