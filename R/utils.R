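# internal helpers shared across modules

# normalize gene symbols: uppercase, trimmed, deduplicated-preserving-order
.normSymbols <- function(x) {
    x <- toupper(trimws(as.character(x)))
    x[nzchar(x)]
}

# split semicolon-joined herb codes into a trimmed character vector
.splitHerbs <- function(x) {
    out <- strsplit(as.character(x), ";", fixed = TRUE)
    lapply(out, function(h) {
        h <- trimws(h)
        unique(h[nzchar(h)])
    })
}

.joinHerbs <- function(h) vapply(h, function(x) paste(sort(x), collapse = ";"),
                                 character(1))

# sniff field separator of a delimited text file (tab beats comma)
.sniffSep <- function(path) {
    first <- readLines(path, n = 1L)
    if (grepl("\t", first)) "\t" else ","
}

# partition items into disjoint blocks keyed by their (sorted, joined) key set
.partitionByKey <- function(items, keys) {
    stopifnot(length(items) == length(keys))
    lab <- vapply(keys, function(k) paste(sort(unique(k)), collapse = "&"),
                  character(1))
    blocks <- split(items, lab)
    blocks[order(names(blocks))]
}

# derive a per-component sub-seed from a master seed (kept below 2^31)
.subSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 48271 + offset * 10007) %% 2147483629)
}

# run code under a local RNG state so callers' streams are untouched
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}
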