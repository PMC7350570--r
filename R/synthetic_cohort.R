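.aa_cache <- new.env(parent = emptyenv())

#' Single-nucleotide-accessible amino-acid substitution table
#'
#' Enumerates every codon-to-codon change differing at exactly one
#' position under the standard genetic code and tabulates the resulting
#' missense amino-acid pairs. The count of codon paths realising a pair
#' is its base weight, so draws from this table stay biologically
#' reachable by one SNV.
#'
#' @return data.frame: \code{ref_aa}, \code{alt_aa}, \code{weight}
#'   (number of codon paths), \code{kd_delta}.
#' @export
aa_substitution_table <- function() {
  if (!is.null(.aa_cache$table)) return(.aa_cache$table)
  codons <- seqinr::words(3)
  aa <- vapply(strsplit(codons, ""), seqinr::translate, character(1))
  pairs <- list()
  for (i in seq_along(codons)) {
    cod <- strsplit(codons[i], "")[[1]]
    for (p in 1:3) for (b in c("a", "c", "g", "t")) {
      if (b == cod[p]) next
      alt <- cod; alt[p] <- b
      aa2 <- seqinr::translate(alt)
      if (aa[i] != "*" && aa2 != "*" && aa[i] != aa2)
        pairs[[length(pairs) + 1]] <- c(aa[i], aa2)
    }
  }
  m <- do.call(rbind, pairs)
  tab <- as.data.frame(table(ref_aa = m[, 1], alt_aa = m[, 2]),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "weight"
  tab <- tab[tab$weight > 0, , drop = FALSE]
  tab$kd_delta <- kd_delta(tab$ref_aa, tab$alt_aa)
  rownames(tab) <- NULL
  .aa_cache$table <- tab
  tab
}

# Exponential tilting: find beta so that the weight * exp(beta * delta)
# distribution over the substitution table has expected delta == target.
tilt_beta <- function(target) {
  tab <- aa_substitution_table()
  d <- tab$kd_delta; w0 <- tab$weight
  if (target <= min(d) || target >= max(d))
    stop("hydro_bias ", target, " outside the achievable KD-delta range (",
         min(d), ", ", max(d), ")")
  f <- function(beta) {
    lw <- log(w0) + beta * d
    w <- exp(lw - max(lw))  # shift in log space for numerical stability
    sum(w * d) / sum(w) - target
  }
  uniroot(f, c(-40, 40), tol = 1e-10)$root
}

#' Draw missense amino-acid pairs with a target hydrophobicity bias
#'
#' Samples (ref, alt) amino-acid pairs from the single-SNV-accessible
#' substitution table, exponentially tilted by Kyte-Doolittle delta so
#' that the expected delta equals \code{hydro_bias} (0 gives an exactly
#' unbiased null).
#'
#' @param n Number of pairs.
#' @param hydro_bias Target expected KD delta.
#' @return data.frame: \code{ref_aa}, \code{alt_aa}, \code{kd_delta}.
#' @export
sample_missense_pairs <- function(n, hydro_bias = 0) {
  tab <- aa_substitution_table()
  beta <- tilt_beta(hydro_bias)
  lw <- log(tab$weight) + beta * tab$kd_delta
  w <- exp(lw - max(lw))
  idx <- sample.int(nrow(tab), n, replace = TRUE, prob = w)
  data.frame(ref_aa = tab$ref_aa[idx], alt_aa = tab$alt_aa[idx],
             kd_delta = tab$kd_delta[idx], stringsAsFactors = FALSE)
}

#' Specification of a synthetic somatic-variant cohort
#'
#' The defaults describe the study conditions this package analyses: 48
#' whole-exome samples from 36 patients, 11 of them face/scalp tumors
#' with high, UV-driven burden, the remainder dominated by the aging
#' (CpG-demethylation) process with a small visceral subgroup carrying a
#' mismatch-repair signature; heavy-tailed per-sample burden (log-normal,
#' hard minimum 8 mutations) averaging about 260 mutations per sample;
#' 61% missense / 31% silent consequences; and a mean missense
#' Kyte-Doolittle shift of +0.924.
#'
#' @param site_groups Named list; per group: \code{n} (samples),
#'   \code{n_patients}, \code{burden} (list: \code{median},
#'   \code{dispersion} = sdlog of the log-normal), \code{mixture} (named
#'   signature mixture summing to 1).
#' @param burden_min Hard minimum mutations per sample.
#' @param consequence_probs Named probabilities over the consequence
#'   classes, summing to 1.
#' @param hydro_bias Target mean KD delta of missense draws.
#' @param capture_size_bp WES capture size per sample (default 38 Mb).
#' @param strand_prob Probability a variant is reported on the pyrimidine
#'   strand (0.5 gives strand-symmetric reporting, so transitions appear
#'   as G>A about as often as C>T).
#' @param seed Integer seed making the simulation fully reproducible.
#' @return A \code{cohort_spec} list.
#' @export
cohort_spec <- function(
    site_groups = list(
      face_scalp = list(n = 11, n_patients = 9,
                        burden = list(median = 500, dispersion = 1.1),
                        mixture = c(Signature.7 = 0.75, Signature.1 = 0.20,
                                    Signature.5 = 0.05)),
      other = list(n = 33, n_patients = 24,
                   burden = list(median = 38, dispersion = 1.0),
                   mixture = c(Signature.1 = 0.75, Signature.5 = 0.15,
                               Signature.16 = 0.10)),
      visceral = list(n = 4, n_patients = 3,
                      burden = list(median = 38, dispersion = 1.0),
                      mixture = c(Signature.6 = 0.45, Signature.20 = 0.25,
                                  Signature.1 = 0.30))),
    burden_min = 8,
    consequence_probs = c(missense = 0.61, silent = 0.31, nonsense = 0.03,
                          splice = 0.02, other = 0.03),
    hydro_bias = 0.924,
    capture_size_bp = 38e6,
    strand_prob = 0.5,
    seed = 1) {
  stopifnot(abs(sum(consequence_probs) - 1) < 1e-8)
  for (g in site_groups) {
    stopifnot(abs(sum(g$mixture) - 1) < 1e-8, g$n >= 0)
    if (!is.null(g$n_patients)) stopifnot(g$n_patients <= max(g$n, 1))
  }
  structure(list(site_groups = site_groups, burden_min = burden_min,
                 consequence_probs = consequence_probs,
                 hydro_bias = hydro_bias, capture_size_bp = capture_size_bp,
                 strand_prob = strand_prob, seed = seed),
            class = "cohort_spec")
}

# Truncated log-normal burden draw (rejection sampling, rounded).
draw_burden <- function(n, median, dispersion, min) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rlnorm(n, meanlog = log(median), sdlog = dispersion))
    out <- c(out, x[x >= min])
  }
  out[seq_len(n)]
}

channel_parts <- function(channel) {
  data.frame(p5 = substr(channel, 1, 1),
             ref = substr(channel, 3, 3),
             alt = substr(channel, 5, 5),
             p3 = substr(channel, 7, 7), stringsAsFactors = FALSE)
}

#' Simulate a somatic-variant cohort with known ground truth
#'
#' Generates a variant table and sample metadata with the statistical
#' structure the downstream analyses assume. Per sample, the mutation
#' count is drawn from the group's truncated log-normal burden model;
#' each variant's 96-channel is drawn from the group's mixture of
#' signature columns (so contexts come directly from the signature
#' reference, no genome needed) and is reported on the pyrimidine or
#' purine strand with probability \code{strand_prob}; the consequence
#' class is drawn from \code{consequence_probs}; missense amino-acid
#' pairs come from the single-SNV-accessible substitution table tilted to
#' the target hydrophobicity bias. Every latent draw is recorded in the
#' ground-truth object, which is sufficient to reconstruct the variant
#' table exactly.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param weights Signature reference matrix (default
#'   \code{\link{synthetic_signature_matrix}()}); every mixture component
#'   named in the spec must be a column.
#' @return A list: \code{variants} (canonical variant data.frame),
#'   \code{meta} (sample metadata), \code{truth} (list: \code{spec},
#'   \code{samples} with latent burden and mixture labels,
#'   \code{variants} with every latent draw).
#' @export
simulate_cohort <- function(spec, weights = synthetic_signature_matrix()) {
  stopifnot(inherits(spec, "cohort_spec"))
  weights <- validate_signature_matrix(weights)
  for (g in spec$site_groups)
    if (length(setdiff(names(g$mixture), colnames(weights))) > 0)
      stop("mixture names a signature absent from the reference matrix")
  set.seed(spec$seed)
  ch <- sbs96_channels()
  empty_variants <- data.frame(
    sample_id = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), context = character(0),
    consequence = character(0), consequence_raw = character(0),
    protein_change = character(0), ref_aa = character(0),
    alt_aa = character(0), aa_pos = integer(0), stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = character(0), patient_id = character(0),
                     site_group = character(0), capture_size_bp = numeric(0),
                     stringsAsFactors = FALSE)
  samples_truth <- data.frame(sample_id = character(0), patient_id = character(0),
                              site_group = character(0), n_mutations = integer(0),
                              stringsAsFactors = FALSE)
  var_list <- list()
  truth_list <- list()
  pat_counter <- 0L
  for (gname in names(spec$site_groups)) {
    g <- spec$site_groups[[gname]]
    if (g$n == 0) next
    n_pat <- if (is.null(g$n_patients)) g$n else g$n_patients
    # first samples get distinct patients, the surplus reuses the earliest
    pat_idx <- c(seq_len(n_pat), rep_len(seq_len(n_pat), g$n - n_pat))
    pat_ids <- sprintf("PT%03d", pat_counter + pat_idx)
    pat_counter <- pat_counter + n_pat
    sample_ids <- sprintf("%s_%02d", toupper(gname), seq_len(g$n))
    burdens <- draw_burden(g$n, g$burden$median, g$burden$dispersion,
                           spec$burden_min)
    meta <- rbind(meta, data.frame(sample_id = sample_ids,
                                   patient_id = pat_ids, site_group = gname,
                                   capture_size_bp = spec$capture_size_bp,
                                   stringsAsFactors = FALSE))
    samples_truth <- rbind(samples_truth,
                           data.frame(sample_id = sample_ids,
                                      patient_id = pat_ids, site_group = gname,
                                      n_mutations = burdens,
                                      stringsAsFactors = FALSE))
    mix <- setNames(rep(0, ncol(weights)), colnames(weights))
    mix[names(g$mixture)] <- g$mixture
    p_channel <- as.numeric(weights %*% mix)
    for (si in seq_len(g$n)) {
      n <- burdens[si]
      channel_idx <- sample.int(96, n, replace = TRUE, prob = p_channel)
      pyrimidine_strand <- runif(n) < spec$strand_prob
      parts <- channel_parts(ch[channel_idx])
      ref <- parts$ref; alt <- parts$alt
      context <- paste0(parts$p5, parts$ref, parts$p3)
      flip <- !pyrimidine_strand
      ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
      alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
      context[flip] <- reverse_complement(context[flip])
      cons <- sample(names(spec$consequence_probs), n, replace = TRUE,
                     prob = spec$consequence_probs)
      ref_aa <- rep(NA_character_, n); alt_aa <- rep(NA_character_, n)
      aa_pos <- rep(NA_integer_, n)
      coding <- cons %in% c("missense", "silent", "nonsense")
      aa_pos[coding] <- sample.int(500, sum(coding), replace = TRUE)
      is_mis <- cons == "missense"
      if (any(is_mis)) {
        pairs <- sample_missense_pairs(sum(is_mis), spec$hydro_bias)
        ref_aa[is_mis] <- pairs$ref_aa; alt_aa[is_mis] <- pairs$alt_aa
      }
      aas <- names(kd_scale())
      is_sil <- cons == "silent"
      if (any(is_sil)) {
        r <- sample(aas, sum(is_sil), replace = TRUE)
        ref_aa[is_sil] <- r; alt_aa[is_sil] <- r
      }
      is_non <- cons == "nonsense"
      if (any(is_non)) {
        ref_aa[is_non] <- sample(aas, sum(is_non), replace = TRUE)
        alt_aa[is_non] <- "*"
      }
      protein_change <- rep(NA_character_, n)
      protein_change[is_mis] <- paste0("p.", ref_aa[is_mis], aa_pos[is_mis],
                                       alt_aa[is_mis])
      protein_change[is_sil] <- paste0("p.", ref_aa[is_sil], aa_pos[is_sil], "=")
      protein_change[is_non] <- paste0("p.", ref_aa[is_non], aa_pos[is_non], "*")
      chrom <- sample(paste0("chr", c(1:22, "X")), n, replace = TRUE)
      pos <- sample.int(2e8, n, replace = TRUE)
      var_list[[length(var_list) + 1]] <- data.frame(
        sample_id = sample_ids[si], chrom = chrom, pos = pos, ref = ref,
        alt = alt, context = context, consequence = cons,
        consequence_raw = cons, protein_change = protein_change,
        ref_aa = ref_aa, alt_aa = alt_aa, aa_pos = aa_pos,
        stringsAsFactors = FALSE)
      truth_list[[length(truth_list) + 1]] <- data.frame(
        sample_id = sample_ids[si], channel_idx = channel_idx,
        pyrimidine_strand = pyrimidine_strand, consequence = cons,
        ref_aa = ref_aa, alt_aa = alt_aa, aa_pos = aa_pos, chrom = chrom,
        pos = pos, stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(var_list) > 0) do.call(rbind, var_list) else empty_variants
  truth_variants <- if (length(truth_list) > 0) do.call(rbind, truth_list) else
    data.frame(sample_id = character(0), channel_idx = integer(0),
               pyrimidine_strand = logical(0), consequence = character(0),
               ref_aa = character(0), alt_aa = character(0),
               aa_pos = integer(0), chrom = character(0), pos = integer(0),
               stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  rownames(truth_variants) <- NULL
  list(variants = variants, meta = meta,
       truth = list(spec = spec, samples = samples_truth,
                    variants = truth_variants))
}

#' Reconstruct the variant table from a ground-truth record
#'
#' Rebuilds every generated variant's alleles and context from the
#' latent draws stored in the ground truth, for reproducibility audits.
#'
#' @param truth The \code{truth} element of \code{\link{simulate_cohort}}.
#' @return A variant data.frame with the same columns and order as the
#'   simulated one.
#' @export
variants_from_truth <- function(truth) {
  tv <- truth$variants
  ch <- sbs96_channels()
  parts <- channel_parts(ch[tv$channel_idx])
  ref <- parts$ref; alt <- parts$alt
  context <- paste0(parts$p5, parts$ref, parts$p3)
  flip <- !tv$pyrimidine_strand
  ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  context[flip] <- reverse_complement(context[flip])
  protein_change <- rep(NA_character_, nrow(tv))
  mis <- tv$consequence == "missense"
  sil <- tv$consequence == "silent"
  non <- tv$consequence == "nonsense"
  protein_change[mis] <- paste0("p.", tv$ref_aa[mis], tv$aa_pos[mis],
                                tv$alt_aa[mis])
  protein_change[sil] <- paste0("p.", tv$ref_aa[sil], tv$aa_pos[sil], "=")
  protein_change[non] <- paste0("p.", tv$ref_aa[non], tv$aa_pos[non], "*")
  data.frame(sample_id = tv$sample_id, chrom = tv$chrom, pos = tv$pos,
             ref = ref, alt = alt, context = context,
             consequence = tv$consequence, consequence_raw = tv$consequence,
             protein_change = protein_change, ref_aa = tv$ref_aa,
             alt_aa = tv$alt_aa, aa_pos = tv$aa_pos, stringsAsFactors = FALSE)
}
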