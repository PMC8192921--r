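#' @useDynLib drivergene, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict rnorm runif plogis sd var
#' @importFrom utils read.csv write.csv
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Default base-to-integer encoding
#'
#' Alphabetical, nonzero encoding so that every sequence position contributes
#' mass to the moment computation. Any injective mapping with four nonzero
#' values is accepted wherever a `mapping` argument appears.
#'
#' @return Named integer vector `c(A = 1, C = 2, G = 3, T = 4)`.
#' @export
default_mapping <- function() {
  c(A = 1L, C = 2L, G = 3L, T = 4L)
}

check_mapping <- function(mapping) {
  if (!all(DNA_BASES %in% names(mapping))) {
    stop("mapping must cover all four bases A, C, G, T", call. = FALSE)
  }
  vals <- as.numeric(mapping[DNA_BASES])
  if (anyDuplicated(vals) || any(vals == 0) || any(!is.finite(vals))) {
    stop("mapping must be injective with nonzero finite values", call. = FALSE)
  }
  invisible(mapping[DNA_BASES])
}

#' Construct a validated nucleotide sequence
#'
#' @param bases Character scalar over the alphabet A/C/G/T (lower case is
#'   folded to upper case before validation).
#' @param id Text identifier.
#' @return An object of class `nt_sequence` with fields `id`, `bases`, `n`.
#' @examples
#' s <- nt_sequence("ACGTACGT", id = "example")
#' s$n
#' @export
nt_sequence <- function(bases, id = "seq") {
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(bases)
  n <- nchar(bases)
  if (n < 4L) {
    stop(sprintf("sequence '%s' has %d bases; at least 4 required", id, n),
         call. = FALSE)
  }
  bad <- gsub("[ACGT]", "", bases)
  if (nzchar(bad)) {
    stop(sprintf("sequence '%s' contains non-ACGT characters: %s",
                 id, paste(unique(strsplit(bad, "")[[1]]), collapse = ",")),
         call. = FALSE)
  }
  structure(list(id = as.character(id), bases = bases, n = n),
            class = "nt_sequence")
}

#' @export
print.nt_sequence <- function(x, ...) {
  shown <- if (x$n > 60) paste0(substr(x$bases, 1, 57), "...") else x$bases
  cat(sprintf("<nt_sequence> %s (%d bp)\n%s\n", x$id, x$n, shown))
  invisible(x)
}

as_nt_sequence <- function(x, id = "seq") {
  if (inherits(x, "nt_sequence")) x else nt_sequence(x, id = id)
}

base_chars <- function(seq) {
  strsplit(as_nt_sequence(seq)$bases, "", fixed = TRUE)[[1]]
}

#' Read sequences from a FASTA file
#'
#' Records are uppercased, then the ambiguity policy is applied to characters
#' outside A/C/G/T (IUPAC ambiguity codes such as N, gaps, anything else):
#' `strict` aborts naming the first offending record; `strip` removes the
#' offending characters and reports the per-record counts via the
#' `stripped` attribute; `fail-record` drops offending records entirely and
#' reports their ids via the `failed` attribute.
#'
#' @param path FASTA file (multi-record; wrapped or unwrapped lines).
#' @param policy One of `"strict"`, `"strip"`, `"fail-record"`.
#' @return List of [nt_sequence] objects. Attributes `stripped` (named integer
#'   vector of removed-character counts) and `failed` (character vector of
#'   skipped record ids) record the policy's actions.
#' @export
read_fasta <- function(path, policy = c("strict", "strip", "fail-record")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf("malformed FASTA file %s: %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  if (length(set) == 0L) stop(sprintf("FASTA file %s contains no records", path), call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  raw <- toupper(as.character(set))
  out <- list()
  stripped <- integer(0)
  failed <- character(0)
  for (i in seq_along(raw)) {
    s <- raw[[i]]
    clean <- gsub("[^ACGT]", "", s)
    n_bad <- nchar(s) - nchar(clean)
    if (n_bad > 0L) {
      if (policy == "strict") {
        stop(sprintf("record '%s' contains %d non-ACGT character(s) under strict policy",
                     ids[[i]], n_bad), call. = FALSE)
      }
      if (policy == "fail-record") {
        failed <- c(failed, ids[[i]])
        next
      }
      stripped[ids[[i]]] <- n_bad
      s <- clean
    }
    if (nchar(s) < 4L) {
      stop(sprintf("record '%s' has %d bases after policy '%s'; at least 4 required",
                   ids[[i]], nchar(s), policy), call. = FALSE)
    }
    out[[length(out) + 1L]] <- nt_sequence(s, id = ids[[i]])
  }
  attr(out, "stripped") <- stripped
  attr(out, "failed") <- failed
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs List of [nt_sequence] (or character vector, optionally named).
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- lapply(seq_along(seqs), function(i) {
    as_nt_sequence(seqs[[i]], id = names(seqs)[i] %||% sprintf("seq%d", i))
  })
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, "", "bases"))
  names(set) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || (length(a) == 1L && is.na(a))) b else a
}

#' Encode a sequence as integers
#'
#' Elementwise substitution of each base by its mapped value, order preserved.
#' This numeric image of the sequence is what the square-grid moments operate
#' on.
#'
#' @param seq [nt_sequence] or character scalar.
#' @param mapping Named base-to-integer table covering A, C, G, T.
#' @return Object of class `encoded_sequence`: list with `values` (numeric
#'   vector of length n) and `mapping`.
#' @examples
#' encode_sequence("ACGT")$values  # 1 2 3 4
#' @export
encode_sequence <- function(seq, mapping = default_mapping()) {
  mapping <- check_mapping(mapping)
  ch <- base_chars(seq)
  structure(list(values = as.numeric(mapping[ch]), mapping = mapping),
            class = "encoded_sequence")
}

#' Decode an encoded sequence back to bases
#' @param enc `encoded_sequence`.
#' @return Character scalar of bases.
#' @export
decode_sequence <- function(enc) {
  stopifnot(inherits(enc, "encoded_sequence"))
  inv <- stats::setNames(names(enc$mapping), as.character(enc$mapping))
  paste(inv[as.character(enc$values)], collapse = "")
}

#' Construct a labeled dataset
#'
#' @param sequences List of [nt_sequence] objects (or character vector).
#' @param labels Binary labels, 1 = driver (positive), 0 = passenger (negative).
#' @return Object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(sequences, labels) {
  if (is.character(sequences)) {
    ids <- names(sequences) %||% sprintf("seq%d", seq_along(sequences))
    sequences <- lapply(seq_along(sequences),
                        function(i) nt_sequence(sequences[[i]], id = ids[[i]]))
  }
  labels <- as.integer(labels)
  if (length(sequences) != length(labels)) {
    stop("sequences and labels must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1", call. = FALSE)
  structure(list(sequences = sequences, labels = labels),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d sequences (%d driver, %d passenger)\n",
              length(x$labels), sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Load a labeled dataset from two FASTA files
#'
#' Mirrors the benchmark convention G = G+ u G-: one file of positive (driver)
#' sequences and one of negative (passenger) sequences.
#'
#' @param pos_fasta,neg_fasta FASTA paths for the positive and negative class.
#' @param policy Ambiguity policy passed to [read_fasta].
#' @return A [labeled_dataset].
#' @export
read_two_class_fasta <- function(pos_fasta, neg_fasta, policy = "strict") {
  pos <- read_fasta(pos_fasta, policy = policy)
  neg <- read_fasta(neg_fasta, policy = policy)
  labeled_dataset(c(pos, neg), c(rep(1L, length(pos)), rep(0L, length(neg))))
}

#' Load a labeled dataset from one FASTA plus a label table
#'
#' @param fasta FASTA path.
#' @param labels_path Two-column tab-delimited file `id<TAB>label`, label 0/1.
#' @param policy Ambiguity policy passed to [read_fasta].
#' @return A [labeled_dataset].
#' @export
read_labeled_fasta <- function(fasta, labels_path, policy = "strict") {
  seqs <- read_fasta(fasta, policy = policy)
  tab <- utils::read.table(labels_path, header = FALSE, sep = "\t",
                           col.names = c("id", "label"),
                           colClasses = c("character", "integer"))
  ids <- vapply(seqs, `[[`, "", "id")
  miss <- setdiff(ids, tab$id)
  if (length(miss) > 0L) {
    stop(sprintf("no label for record(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  labeled_dataset(seqs, tab$label[match(ids, tab$id)])
}

#' Generate a synthetic labeled dataset
#'
#' Stand-in for a curated driver/passenger benchmark. The positive class is
#' drawn from a base-composition distribution shifted toward G/C by
#' `separation` and carries a fixed 6-mer motif (`GGCGCC`) planted at a random
#' position with probability `separation`; the negative class is drawn from
#' the complementary A/T-shifted composition. `separation = 0` gives two
#' statistically indistinguishable uniform-composition classes (a null
#' dataset); `separation = 1` gives a strongly separable dataset. Identical
#' seeds give identical datasets.
#'
#' @param n_pos,n_neg Class sizes (>= 1).
#' @param length Sequence length in bases (>= 20).
#' @param separation Effect size in \[0, 1\].
#' @param seed Integer seed; fully determines the output.
#' @return A [labeled_dataset] with ids `pos_i` / `neg_i`.
#' @export
generate_synthetic_dataset <- function(n_pos, n_neg, length = 300L,
                                       separation = 0.5, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, length >= 20L)
  if (!is.numeric(separation) || separation < 0 || separation > 1) {
    stop("separation must be in [0, 1]", call. = FALSE)
  }
  motif <- "GGCGCC"
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  p_pos <- c(A = (1 - separation) / 4, C = (1 + separation) / 4,
             G = (1 + separation) / 4, T = (1 - separation) / 4)
  p_neg <- c(A = (1 + separation) / 4, C = (1 - separation) / 4,
             G = (1 - separation) / 4, T = (1 + separation) / 4)
  draw <- function(probs, plant_motif) {
    ch <- sample(DNA_BASES, length, replace = TRUE, prob = probs)
    if (plant_motif && stats::runif(1) < separation) {
      at <- sample.int(length - nchar(motif) + 1L, 1L)
      ch[at:(at + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]
    }
    paste(ch, collapse = "")
  }
  seqs <- vector("list", n_pos + n_neg)
  for (i in seq_len(n_pos)) {
    seqs[[i]] <- nt_sequence(draw(p_pos, TRUE), id = sprintf("pos_%d", i))
  }
  for (i in seq_len(n_neg)) {
    seqs[[n_pos + i]] <- nt_sequence(draw(p_neg, FALSE), id = sprintf("neg_%d", i))
  }
  labeled_dataset(seqs, c(rep(1L, n_pos), rep(0L, n_neg)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}
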