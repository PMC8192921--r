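#' Frequency vector (base composition)
#'
#' Per-base occurrence counts in the fixed order A, C, G, T. Counts sum to the
#' sequence length.
#'
#' @param seq [nt_sequence] or character scalar.
#' @return Named non-negative integer vector of length 4.
#' @examples
#' frequency_vector("ACGTACGT")
#' @export
frequency_vector <- function(seq) {
  ch <- base_chars(seq)
  vapply(DNA_BASES, function(b) sum(ch == b), integer(1))
}

#' Accumulative absolute position incidence vector (AAPIV)
#'
#' For each base, the sum of all 1-based positions at which it occurs. The
#' four sums partition 1..n, so they total n(n+1)/2.
#'
#' @param seq [nt_sequence] or character scalar.
#' @return Named numeric vector of length 4 in base order A, C, G, T.
#' @examples
#' aapiv("AAGA")  # A: 1+2+4 = 7, G: 3
#' @export
aapiv <- function(seq) {
  ch <- base_chars(seq)
  pos <- seq_along(ch)
  vapply(DNA_BASES, function(b) sum(pos[ch == b]), numeric(1))
}

#' Reverse AAPIV (RAAPIV)
#'
#' [aapiv] applied to the reversed sequence; equivalently, position sums under
#' the reflection j -> n+1-j, so raapiv_i = counts_i * (n+1) - aapiv_i.
#'
#' @param seq [nt_sequence] or character scalar.
#' @return Named numeric vector of length 4 in base order A, C, G, T.
#' @export
raapiv <- function(seq) {
  ch <- rev(base_chars(seq))
  pos <- seq_along(ch)
  vapply(DNA_BASES, function(b) sum(pos[ch == b]), numeric(1))
}

reverse_bases <- function(seq) {
  s <- as_nt_sequence(seq)
  nt_sequence(paste(rev(base_chars(s)), collapse = ""),
              id = paste0(s$id, "_rev"))
}

#' Position relative incidence matrix (PRIM)
#'
#' 4x4 matrix R\[p, q\] aggregating the positions of base q relative to the
#' first occurrence of base p. Under the default `"signed"` convention
#' R\[p, q\] = sum over occurrences j of q of (j - firstpos(p)); the
#' `"absolute"` convention sums |j - firstpos(p)| instead. If base p never
#' occurs its row is zero; if base q never occurs the entry is zero (empty
#' sum). Rows and columns follow the fixed base order A, C, G, T.
#'
#' @param seq [nt_sequence] or character scalar.
#' @param convention `"signed"` (default) or `"absolute"`.
#' @return Object of class `incidence_matrix`: 4x4 numeric matrix with
#'   attribute `kind = "PRIM"`.
#' @examples
#' prim("ACGT")["A", ]  # 0 1 2 3
#' @export
prim <- function(seq, convention = c("signed", "absolute")) {
  convention <- match.arg(convention)
  ch <- base_chars(seq)
  pos <- seq_along(ch)
  m <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  for (p in DNA_BASES) {
    where_p <- pos[ch == p]
    if (length(where_p) == 0L) next
    fp <- where_p[[1]]
    for (q in DNA_BASES) {
      where_q <- pos[ch == q]
      if (length(where_q) == 0L) next
      m[p, q] <- if (convention == "signed") {
        sum(where_q - fp)
      } else {
        sum(abs(where_q - fp))
      }
    }
  }
  structure(m, class = c("incidence_matrix", class(m)), kind = "PRIM",
            convention = convention)
}

#' Reverse PRIM (RPRIM)
#'
#' [prim] of the reversed sequence.
#'
#' @inheritParams prim
#' @return Object of class `incidence_matrix` with attribute `kind = "RPRIM"`.
#' @export
rprim <- function(seq, convention = c("signed", "absolute")) {
  convention <- match.arg(convention)
  m <- prim(reverse_bases(seq), convention = convention)
  attr(m, "kind") <- "RPRIM"
  m
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("<incidence_matrix> %s (%s convention)\n",
              attr(x, "kind"), attr(x, "convention")))
  print(matrix(as.numeric(x), 4, 4, dimnames = dimnames(x)))
  invisible(x)
}
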