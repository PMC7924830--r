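#' Read / write aligned sequences as a tibble
#'
#' Thin FASTA wrappers around \pkg{ape}: IDs are taken up to the first
#' whitespace, wrapped sequence lines are accepted, and sequences come
#' back upper-case. An optional two-column CSV (`id`, `group`) attaches
#' clade/group labels.
#'
#' @param path FASTA file.
#' @param group_csv optional CSV path with columns `id` and `group`.
#' @return Tibble with columns `id`, `seq` (and `group` when mapped).
#' @export
read_fasta <- function(path, group_csv = NULL) {
  dna <- ape::read.FASTA(path)
  out <- tibble(
    id = sub("\\s.*$", "", names(dna)),
    seq = unname(toupper(vapply(as.character(dna), paste, character(1),
                                collapse = "")))
  )
  if (!is.null(group_csv)) {
    gm <- read.csv(group_csv, stringsAsFactors = FALSE)
    out$group <- gm$group[match(out$id, gm$id)]
  }
  out
}

#' @rdname read_fasta
#' @param aln alignment tibble with `id` and `seq` columns.
#' @export
write_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln)))
    writeLines(c(paste0(">", aln$id[i]), aln$seq[i]), con)
  invisible(path)
}

check_alignment <- function(aln) {
  if (nrow(aln) == 0) abort("empty alignment")
  len <- nchar(aln$seq)
  if (length(unique(len)) != 1)
    abort("ragged alignment: sequences differ in length")
  invisible(len[1])
}

#' Collapse an alignment to unique haplotypes
#'
#' Sequences are compared case-insensitively by exact string equality;
#' the first-seen sequence represents each haplotype.
#'
#' @param aln alignment tibble (`id`, `seq`).
#' @return List with `n_unique` and `haplotypes`, a tibble mapping every
#'   `id` to its `haplotype` index and `representative` id.
#' @export
dedupe_haplotypes <- function(aln) {
  check_alignment(aln)
  key <- toupper(aln$seq)
  hap <- match(key, unique(key))
  list(
    n_unique = length(unique(key)),
    haplotypes = tibble(
      id = aln$id,
      haplotype = hap,
      representative = aln$id[match(hap, hap)]
    )
  )
}

AMBIG_OK <- c("A", "C", "G", "T")

#' Uncorrected pairwise p-distance
#'
#' Proportion of differing sites between two equal-length aligned
#' sequences, with pairwise deletion: columns where either sequence holds
#' a gap or an ambiguity code (anything outside A/C/G/T) are excluded.
#'
#' @param a,b aligned sequences (strings of equal length).
#' @return Proportion in `[0, 1]`.
#' @examples
#' p_distance("ACGT", "ACGA") # 0.25
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("sequences differ in length")
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  ok <- av %in% AMBIG_OK & bv %in% AMBIG_OK
  if (!any(ok)) abort("no comparable sites (all gapped or ambiguous)")
  sum(av[ok] != bv[ok]) / sum(ok)
}

#' Mean between-group nucleotide distance
#'
#' Arithmetic mean of the pairwise distance over all cross-group sequence
#' pairs. The default metric is the uncorrected p-distance with pairwise
#' deletion; `method = "TN93"` instead uses the Tamura-Nei 1993 corrected
#' distance (via [ape::dist.dna()]), the substitution model typically
#' selected for these mitochondrial alignments.
#'
#' @param aln alignment tibble with `id`, `seq` and `group` columns.
#' @param g1,g2 group labels.
#' @param method `"p"` (default) or `"TN93"`.
#' @return Mean cross-group distance (proportion).
#' @export
between_group_distance <- function(aln, g1, g2, method = c("p", "TN93")) {
  method <- match.arg(method)
  check_alignment(aln)
  i1 <- which(aln$group == g1)
  i2 <- which(aln$group == g2)
  if (!length(i1)) abort(paste0("group absent from alignment: ", g1))
  if (!length(i2)) abort(paste0("group absent from alignment: ", g2))
  if (method == "p") {
    mean(vapply(i1, function(i)
      vapply(i2, function(j) p_distance(aln$seq[i], aln$seq[j]), numeric(1)),
      numeric(length(i2))))
  } else {
    dna <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(aln$seq), "")))
    rownames(dna) <- aln$id
    dm <- as.matrix(ape::dist.dna(dna, model = "TN93",
                                  pairwise.deletion = TRUE))
    mean(dm[i1, i2])
  }
}

#' Convert an evolutionary rate between genes
#'
#' Rescales a reference gene's substitution rate to a target gene by the
#' ratio of their mean evolutionary distances over the same samples:
#' `target_rate = reference_rate * d_target / d_ref`. Used to carry the
#' widely cited cytochrome b rate (0.76 %/site/My) over to ND2.
#'
#' @param reference_rate reference-gene rate (e.g. %/site/My).
#' @param d_ref mean distance of the reference gene (> 0).
#' @param d_target mean distance of the target gene.
#' @return Target-gene rate, in the units of `reference_rate`.
#' @examples
#' round(convert_rate(0.76, 0.0513, 0.0627), 2) # 0.93
#' @export
convert_rate <- function(reference_rate, d_ref, d_target) {
  if (d_ref <= 0) abort("d_ref must be > 0")
  reference_rate * d_target / d_ref
}
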