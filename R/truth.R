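SNP_CLASSES <- c("AT>GC", "GC>AT", "AT>CG", "AT>TA", "GC>CG", "GC>TA")

# For each strand-symmetric class, the substitution applied to an A/G base;
# the T/C counterpart is the complement.
class_alt <- function(class, ref) {
  target <- switch(class,
    `AT>GC` = c(A = "G", T = "C"),
    `GC>AT` = c(G = "A", C = "T"),
    `AT>CG` = c(A = "C", T = "G"),
    `AT>TA` = c(A = "T", T = "A"),
    `GC>CG` = c(G = "C", C = "G"),
    `GC>TA` = c(G = "T", C = "A"),
    stop("unknown SNP class: ", class))
  unname(target[ref])
}

empty_truth <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
              alt = character(0), vtype = character(0), class = character(0),
              origin = character(0), group = character(0),
              stringsAsFactors = FALSE)
}

# Sample n variants (SNPs by spectrum + anchored indels) at unique positions.
sample_variants <- function(ref, n, spectrum, indel_fraction, avoid = integer(0)) {
  host <- chars(ref$host)
  L <- length(host)
  eligible <- setdiff(seq_len(L - 4L)[-1L], avoid)  # keep 1 bp anchor room
  if (n > length(eligible)) stop("n exceeds the number of eligible sites")
  is_indel <- stats::runif(n) < indel_fraction
  n_snp <- sum(!is_indel)
  classes <- if (n_snp > 0)
    sample(SNP_CLASSES, n_snp, replace = TRUE, prob = spectrum) else character(0)

  at_pos <- eligible[host[eligible] %in% c("A", "T")]
  gc_pos <- eligible[host[eligible] %in% c("G", "C")]
  need_at <- sum(startsWith(classes, "AT"))
  need_gc <- n_snp - need_at
  n_ind <- sum(is_indel)
  if (need_at > length(at_pos) || need_gc > length(gc_pos))
    stop("n exceeds the number of eligible sites for the requested spectrum")
  pos_at <- sample(at_pos, need_at)
  pos_gc <- sample(gc_pos, need_gc)
  pos_ind <- sample(setdiff(eligible, c(pos_at, pos_gc)), n_ind)

  out <- vector("list", n)
  snp_pos <- integer(n_snp)
  snp_pos[startsWith(classes, "AT")] <- pos_at
  snp_pos[!startsWith(classes, "AT")] <- pos_gc

  rows <- list()
  if (n_snp > 0) {
    refb <- host[snp_pos]
    altb <- vapply(seq_len(n_snp), function(i) class_alt(classes[i], refb[i]),
                   character(1))
    rows$snp <- data.frame(chrom = ref$chrom, pos = snp_pos, ref = refb,
                           alt = altb, vtype = "SNP", class = classes,
                           stringsAsFactors = FALSE)
  }
  if (n_ind > 0) {
    del <- stats::runif(n_ind) < 0.5
    len <- sample(1:3, n_ind, replace = TRUE)
    anchor <- host[pos_ind]
    refa <- character(n_ind); alta <- character(n_ind)
    for (i in seq_len(n_ind)) {
      if (del[i]) {
        refa[i] <- paste(host[pos_ind[i]:(pos_ind[i] + len[i])], collapse = "")
        alta[i] <- anchor[i]
      } else {
        refa[i] <- anchor[i]
        alta[i] <- paste0(anchor[i], random_dna(len[i], 0.5))
      }
    }
    rows$indel <- data.frame(chrom = ref$chrom, pos = pos_ind, ref = refa,
                             alt = alta,
                             vtype = ifelse(del, "deletion", "insertion"),
                             class = NA_character_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$pos), , drop = FALSE]
}

#' Induce T0 somaclonal mutations
#'
#' Draws `n` mutations for one T0 regenerant: unique positions, SNP classes
#' from the six-class strand-symmetric spectrum, indels (1-3 bp, anchored)
#' at the configured fraction. All start heterozygous in the T0 plant.
#'
#' @param ref A `ReferenceBundle`.
#' @param n Number of mutations.
#' @param spectrum Named weights over the six SNP classes (sum to 1).
#' @param indel_fraction Fraction of mutations that are indels.
#' @param group Sibling-group label of the T0 plant the mutations belong to.
#' @param seed Integer seed.
#' @param avoid Positions to exclude (e.g. already used by another truth set).
#' @return A truth data.frame (chrom, pos, ref, alt, vtype, class, origin,
#'   group), origin = "induced_T0".
#' @export
induce_t0_mutations <- function(ref, n, spectrum = default_spectrum(),
                                indel_fraction = 0, group = "T0", seed = 1L,
                                avoid = integer(0)) {
  if (any(spectrum < 0) || abs(sum(spectrum) - 1) > 1e-8)
    stop("spectrum weights must be non-negative and sum to 1")
  set.seed(seed)
  if (n == 0) return(empty_truth())
  v <- sample_variants(ref, n, spectrum[SNP_CLASSES], indel_fraction, avoid)
  v$origin <- "induced_T0"
  v$group <- group
  rownames(v) <- NULL
  v
}

#' Background polymorphisms between the study line and the reference genome
#'
#' Variants that distinguish the laboratory cultivar from the reference
#' assembly: present homozygous-alternate in every line, shared across
#' sibling groups, and therefore removable by the shared-variant subtraction.
#'
#' @inheritParams induce_t0_mutations
#' @return A truth data.frame with origin = "background_polymorphism".
#' @export
background_polymorphisms <- function(ref, n, spectrum = default_spectrum(),
                                     indel_fraction = 0.13, seed = 2L,
                                     avoid = integer(0)) {
  set.seed(seed)
  if (n == 0) return(empty_truth())
  v <- sample_variants(ref, n, spectrum[SNP_CLASSES], indel_fraction, avoid)
  v$origin <- "background_polymorphism"
  v$group <- NA_character_
  rownames(v) <- NULL
  v
}

#' Segregate truth variants through selfing generations
#'
#' Fills per-line zygosity. Each induced mutation is heterozygous in its T0
#' plant; per selfing round it fixes to homozygous mutant with probability
#' 1/4, stays heterozygous with 1/2, and is lost with 1/4, independently per
#' variant per lineage. Sibling lines share the T0 ancestor but segregate
#' independently from the first round on. Mutations of one sibling group are
#' homozygous-reference in all other lines; background polymorphisms are
#' homozygous-alternate everywhere.
#'
#' @param truth Truth data.frame (rbind of induced + background sets).
#' @param plans Line-plan data.frame (see [default_line_plans()]).
#' @param seed Integer seed.
#' @return `truth` with one `zyg_<line>` column per line, values in
#'   {"hom_ref", "het", "hom_alt"}.
#' @export
segregate <- function(truth, plans, seed = 3L) {
  validate_line_plans(plans)
  set.seed(seed)
  n <- nrow(truth)
  for (i in seq_len(nrow(plans))) {
    line <- plans$name[i]
    g <- plans$generation[i]
    zyg <- rep("hom_ref", n)
    bg <- truth$origin == "background_polymorphism"
    zyg[bg] <- "hom_alt"
    own <- which(truth$origin == "induced_T0" &
                 truth$group == plans$sibling_group[i])
    state <- rep("het", length(own))
    for (round in seq_len(g)) {
      u <- stats::runif(length(own))
      still <- state == "het"
      state[still & u < 0.25] <- "hom_alt"
      state[still & u > 0.75] <- "hom_ref"
    }
    zyg[own] <- state
    truth[[paste0("zyg_", line)]] <- zyg
  }
  truth
}
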