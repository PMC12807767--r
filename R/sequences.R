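## Small sequence utilities shared by the variant engine and the
## nomenclature layer.  Sequences are plain upper-case character strings;
## Biostrings does the biochemistry.

## standard genetic code, taken once from Biostrings ("*" = stop)
.codon_table <- Biostrings::GENETIC_CODE

revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", x))))
}

## translate, tolerating a trailing partial codon (dropped); stops are "*"
aa_translate <- function(nt) {
  n <- nchar(nt)
  if (n < 3L) return("")
  k <- n %/% 3L
  codons <- substring(nt, 3L * (seq_len(k) - 1L) + 1L, 3L * seq_len(k))
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## substring by 0-based half-open genomic coords given the window offset
win_substr <- function(win, woff, s, e) {
  if (e <= s) return("")
  substr(win, s - woff + 1L, e - woff)
}

## genomic span replaced by a variant (anchor base excluded for indels),
## plus the replacement string
variant_edit <- function(v) {
  rlen <- nchar(v$ref); alen <- nchar(v$alt)
  if (rlen == 1L && alen == 1L)
    list(rs = v$pos, re = v$pos + 1L, repl = v$alt)
  else
    list(rs = v$pos + 1L, re = v$pos + rlen,
         repl = substr(v$alt, 2L, alen))
}

## apply a variant table to one interval [s, e) of the reference window.
## Variants must be fully contained (anchor may sit on the left edge - 1 for
## pure indels whose edit starts at s).
apply_variants_interval <- function(win, woff, s, e, vars) {
  if (is.null(vars) || nrow(vars) == 0L) return(win_substr(win, woff, s, e))
  vars <- vars[order(vars$pos), , drop = FALSE]
  out <- character(0)
  cur <- s
  for (i in seq_len(nrow(vars))) {
    ed <- variant_edit(vars[i, ])
    if (ed$re <= s || ed$rs >= e) next
    if (ed$rs < s || ed$re > e)
      stop("variant at pos ", vars$pos[i], " crosses a region boundary")
    if (ed$rs < cur)
      stop("overlapping variants at pos ", vars$pos[i])
    out <- c(out, win_substr(win, woff, cur, ed$rs), ed$repl)
    cur <- ed$re
  }
  paste0(paste(out, collapse = ""), win_substr(win, woff, cur, e))
}

## sequence of a set of intervals with variants applied, transcript order
## (concatenated 5'->3' on the transcript strand)
region_sequence <- function(iv, win, woff, strand, vars = NULL) {
  if (is.null(dim(iv))) iv <- data.frame(start = iv[1], end = iv[2])
  if (nrow(iv) == 0L) return(NA_character_)
  pieces <- vapply(seq_len(nrow(iv)), function(i)
    apply_variants_interval(win, woff, iv$start[i], iv$end[i], vars),
    character(1))
  s <- paste(pieces, collapse = "")
  if (strand == "-") revcomp(s) else s
}

## maximal run of identical bases containing 1-based position i
run_length_at <- function(seq, i) {
  n <- nchar(seq)
  if (i < 1L || i > n) return(1L)
  b <- substr(seq, i, i)
  l <- i
  while (l > 1L && substr(seq, l - 1L, l - 1L) == b) l <- l - 1L
  r <- i
  while (r < n && substr(seq, r + 1L, r + 1L) == b) r <- r + 1L
  r - l + 1L
}
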