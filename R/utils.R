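BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

# reverse complement of a plain character string (A/C/G/T/N)
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# encode a sequence string as integers 1..4 (A,C,G,T); other letters -> NA
encode_seq <- function(s) {
  match(strsplit(toupper(s), "")[[1]], BASES)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

read_tsv_strict <- function(path, required = character()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  miss <- setdiff(required, names(x))
  if (length(miss) > 0)
    stopf("%s: missing required column(s): %s", path,
          paste(miss, collapse = ", "))
  x
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
}
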