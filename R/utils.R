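## reverse complement for plain character vectors
.revcompChar <- function(x) {
    if (length(x) == 0L) return(character(0))
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## read a FASTQ file into a named character vector of sequences
.readFastqSeqs <- function(path) {
    if (!file.exists(path)) stop("FASTQ file not found: ", path)
    set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
        error = function(e) stop("failed to parse FASTQ '", path, "': ",
                                 conditionMessage(e)))
    out <- as.character(set)
    names(out) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
    out
}
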