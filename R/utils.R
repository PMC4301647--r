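# internal helpers

# byte-wise a <= b (C locale), prefix of the other counts as smaller
.byteLE <- function(a, b) {
  ra <- utf8ToInt(a); rb <- utf8ToInt(b)
  n <- min(length(ra), length(rb))
  if (n > 0L) {
    d <- ra[seq_len(n)] - rb[seq_len(n)]
    i <- which(d != 0L)[1]
    if (!is.na(i)) return(d[i] < 0L)
  }
  length(ra) <= length(rb)
}

# reverse complement of a plain character string
.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# round half away from zero (base round() rounds half to even)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# condition labels of a design data.frame (sample, condition), in the order
# of the expression matrix columns
.conditionOf <- function(design, samples) {
  idx <- match(samples, design$sample)
  if (anyNA(idx)) stop("samples missing from design: ",
                       paste(samples[is.na(idx)], collapse = ", "))
  design$condition[idx]
}
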