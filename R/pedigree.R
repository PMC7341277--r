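#' Genotype state space
#'
#' A single autosomal diallelic locus with wild allele A and mutated allele B.
#' The three genotype states are always reported in the fixed order
#' AA, AB, BB.
#'
#' @return `c("AA", "AB", "BB")`.
#' @export
genotype_states <- function() c("AA", "AB", "BB")

#' Probability that a parent transmits the mutated allele
#'
#' Mendelian segregation at a single locus: AA transmits B with probability
#' 0, AB with 1/2, BB with 1.
#'
#' @param g Genotype, one of `"AA"`, `"AB"`, `"BB"`.
#' @return A single probability.
#' @export
gamete_prob <- function(g) {
  if (!is.character(g) || length(g) != 1L || !(g %in% genotype_states()))
    stop_validation("genotype must be one of AA, AB, BB")
  c(AA = 0, AB = 0.5, BB = 1)[[g]]
}

#' Mendelian transmission distribution for an offspring
#'
#' With transmission probabilities \eqn{b_s} and \eqn{b_d} for the sire and
#' dam, the offspring is BB with probability \eqn{b_s b_d}, AA with
#' \eqn{(1-b_s)(1-b_d)}, and AB otherwise. Symmetric in its arguments.
#'
#' @param g_sire,g_dam Parental genotypes.
#' @return Named probability vector over `c("AA", "AB", "BB")`, summing to 1.
#' @examples
#' mendelian_transmission("AB", "AB")  # 0.25, 0.50, 0.25
#' @export
mendelian_transmission <- function(g_sire, g_dam) {
  bs <- gamete_prob(g_sire)
  bd <- gamete_prob(g_dam)
  c(AA = (1 - bs) * (1 - bd),
    AB = bs * (1 - bd) + bd * (1 - bs),
    BB = bs * bd)
}

#' Hardy-Weinberg genotype prior
#'
#' Genotype frequencies implied by a mutant-allele frequency `q` under random
#' mating: \eqn{((1-q)^2,\ 2q(1-q),\ q^2)}.
#'
#' @param q Mutant (B) allele frequency in [0, 1].
#' @return Named probability vector over `c("AA", "AB", "BB")`.
#' @export
hwe_prior <- function(q) {
  assert_probability(q, "allele frequency q")
  c(AA = (1 - q)^2, AB = 2 * q * (1 - q), BB = q^2)
}

# Parse a founder genotype-prior specification into a named probability
# vector. Accepted forms: "uniform"; "hwe(q)" or list(hwe = q);
# a fixed state "AA"/"AB"/"BB" or list(fixed = state); a numeric 3-vector.
parse_genotype_prior <- function(x) {
  gs <- genotype_states()
  if (is.numeric(x)) {
    if (length(x) != 3L || any(!is.finite(x)) || any(x < 0) ||
        abs(sum(x) - 1) > 1e-12)
      stop_validation("numeric genotype prior must be 3 probabilities summing to 1")
    return(stats::setNames(as.numeric(x), gs))
  }
  if (is.list(x)) {
    if (!is.null(x$hwe)) return(hwe_prior(x$hwe))
    if (!is.null(x$fixed)) x <- x$fixed
    else stop_validation("unrecognized genotype prior specification")
  }
  if (is.character(x) && length(x) == 1L) {
    if (x == "uniform") return(stats::setNames(rep(1 / 3, 3), gs))
    m <- regmatches(x, regexec("^hwe\\(([0-9.eE+-]+)\\)$", x))[[1]]
    if (length(m) == 2L) return(hwe_prior(as.numeric(m[2])))
    if (x %in% gs) return(stats::setNames(as.numeric(gs == x), gs))
  }
  stop_validation("unrecognized genotype prior specification: %s",
                  paste(deparse(x), collapse = ""))
}
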