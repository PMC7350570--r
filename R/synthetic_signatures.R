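# Run expr under a temporary RNG state so fixed internal constructions
# never disturb the caller's random stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Spread `mass` over the given channels (uniformly) on top of a flat
# baseline of (1 - mass); returns a normalised 96-vector.
peaked_signature <- function(channels, mass) {
  ch <- sbs96_channels()
  w <- rep((1 - mass) / 96, 96)
  names(w) <- ch
  idx <- match(channels, ch)
  stopifnot(!anyNA(idx))
  w[idx] <- w[idx] + mass / length(idx)
  w / sum(w)
}

channels_matching <- function(sub, p5 = NUCLEOTIDES, p3 = NUCLEOTIDES) {
  as.vector(outer(p5, p3, function(a, b) paste0(a, "[", sub, "]", b)))
}

#' A synthetic 30-signature reference matrix
#'
#' Builds a deterministic, fully synthetic 96 x 30 signature matrix with
#' COSMIC-v2-style column names (\code{Signature.1} ... \code{Signature.30}).
#' The columns annotated with known etiologies in the shipped etiology map
#' are given the characteristic channel concentrations of their processes
#' (aging: C>T at NpCpG; UV: C>T at dipyrimidine 5' contexts; APOBEC: C>T /
#' C>G at TpCpW; MMR: broad C>T and T>C patterns; POLE: C>A at TpCpT;
#' POLH: broad T>A / T>C); the remaining columns are fixed random
#' probability vectors. This is a synthetic stand-in with the same shape
#' and semantics as a COSMIC v2 matrix, intended for simulation and
#' testing; for real cohorts supply the published matrix via
#' \code{\link{read_signature_matrix}}.
#'
#' @param n_signatures Number of columns, at most 30 (default 30).
#' @return Validated 96 x K matrix.
#' @export
synthetic_signature_matrix <- function(n_signatures = 30) {
  stopifnot(n_signatures >= 1, n_signatures <= 30)
  named <- list(
    Signature.1  = peaked_signature(channels_matching("C>T", p3 = "G"), 0.85),
    Signature.2  = peaked_signature(channels_matching("C>T", p5 = "T",
                                                      p3 = c("A", "T")), 0.80),
    Signature.6  = peaked_signature(c(channels_matching("C>T", p5 = "G"),
                                      channels_matching("T>C", p3 = "C")), 0.75),
    Signature.7  = peaked_signature(channels_matching("C>T",
                                                      p5 = c("C", "T")), 0.90),
    Signature.9  = peaked_signature(c(channels_matching("T>A"),
                                      channels_matching("T>C", p5 = "A")), 0.70),
    Signature.10 = peaked_signature(c(channels_matching("C>A", p5 = "T",
                                                        p3 = "T"),
                                      channels_matching("C>T", p5 = "T",
                                                        p3 = "G")), 0.85),
    Signature.13 = peaked_signature(channels_matching("C>G", p5 = "T",
                                                      p3 = c("A", "T")), 0.80),
    Signature.15 = peaked_signature(c(channels_matching("C>T", p3 = "T"),
                                      channels_matching("C>G", p5 = "G")), 0.70),
    Signature.20 = peaked_signature(c(channels_matching("C>T", p5 = "G",
                                                        p3 = "C"),
                                      channels_matching("T>C", p5 = "T")), 0.70),
    Signature.26 = peaked_signature(channels_matching("T>C", p3 = "G"), 0.75))
  all_names <- paste0("Signature.", seq_len(30))
  W <- with_local_seed(76540321, {
    m <- matrix(0, nrow = 96, ncol = 30,
                dimnames = list(sbs96_channels(), all_names))
    for (nm in all_names) {
      if (nm %in% names(named)) {
        m[, nm] <- named[[nm]]
      } else {
        g <- stats::rgamma(96, shape = 0.5)
        m[, nm] <- g / sum(g)
      }
    }
    m
  })
  validate_signature_matrix(W[, seq_len(n_signatures), drop = FALSE])
}
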