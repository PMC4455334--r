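`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a FASTA index (.fai-style) name/length table
#'
#' Accepts a `samtools faidx`-style file (name, length, offset, ...); only the
#' first two columns are used.
#'
#' @param path Path to a `.fai` file or any tab-separated table whose first
#'   two columns are sequence name and length.
#' @return Named numeric vector of sequence lengths.
#' @export
read_fai <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

## Coerce the various ways a reference index can be supplied (named vector,
## data.frame, .fai path, DNAStringSet) to a named length vector.
as_seqlengths <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(read_fai(x))
  if (inherits(x, "DNAStringSet"))
    return(stats::setNames(as.numeric(Biostrings::width(x)), names(x)))
  if (is.data.frame(x))
    return(stats::setNames(as.numeric(x[[2]]), as.character(x[[1]])))
  if (is.numeric(x) && !is.null(names(x)))
    return(x)
  stop("cannot interpret reference index; supply a named length vector, ",
       "a two-column data.frame, a .fai path or a DNAStringSet")
}

## 0-based window start positions tiling a sequence of length L.
## Trailing bases shorter than window_size are dropped.
window_starts <- function(L, window_size, step) {
  if (L < window_size) return(numeric(0))
  seq(0, by = step, length.out = (L - window_size) %/% step + 1L)
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a non-missing scalar", name))
  invisible(x)
}
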