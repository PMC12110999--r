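# Founder-label dropping and the IBD state space.
#
# Every founder carries two distinct haplotype labels. An IBD vector has
# one bit per meiosis (frozen order: sorted by child, paternal before
# maternal); bit 0 transmits the parent's paternal haplotype, bit 1 the
# maternal one. Dropping labels through the pedigree yields each subject's
# two labels; the pair is IBD1 when exactly one label is shared, IBD2 when
# both are.

capacity_error <- function(msg) {
  stop(errorCondition(msg, class = c("contibd_capacity_error", "error",
                                     "condition")))
}

validation_error <- function(msg) {
  stop(errorCondition(msg, class = c("contibd_validation_error", "error",
                                     "condition")))
}

# Number of labels shared by the pair for one full IBD vector (0, 1 or 2).
drop_labels_count <- function(ped, v) {
  n <- length(ped$id)
  pat <- integer(n); mat <- integer(n)
  for (i in ped$founders) {
    pat[i] <- 2L * i - 1L
    mat[i] <- 2L * i
  }
  mrow <- ped$meioses
  for (j in ped$topo) {
    if (is.na(ped$father_idx[j])) next
    kp <- which(mrow$child == j & mrow$type == "paternal")
    km <- which(mrow$child == j & mrow$type == "maternal")
    f <- ped$father_idx[j]; m <- ped$mother_idx[j]
    pat[j] <- if (v[kp] == 0L) pat[f] else mat[f]
    mat[j] <- if (v[km] == 0L) pat[m] else mat[m]
  }
  a <- ped$pair[1]; b <- ped$pair[2]
  length(intersect(c(pat[a], mat[a]), c(pat[b], mat[b])))
}

#' IBD state implied by an IBD vector
#'
#' Evaluates, by founder-label dropping, whether the studied pair is IBD1
#' under a full IBD (inheritance) vector: one bit per meiosis, ordered by
#' child (paternal before maternal), 0 transmitting the parent's paternal
#' haplotype and 1 the maternal one.
#'
#' @param ped an [ibd_pedigree()].
#' @param v integer vector of 0/1 bits of length `2 * ped$nnf`.
#' @return 1 if the pair shares exactly one founder haplotype label, else 0.
#' @export
ibd_state <- function(ped, v) {
  ped <- as_ibd_pedigree(ped)
  if (length(v) != 2L * ped$nnf) {
    stop("IBD vector has length ", length(v), " but the pedigree has ",
         2L * ped$nnf, " meioses")
  }
  if (!all(v %in% c(0L, 1L))) stop("IBD vector must be binary")
  n <- drop_labels_count(ped, as.integer(v))
  if (n >= 1L) 1L else 0L
}

# Reduced IBD model: the IBD process depends only on the relevant meioses
# (see relevant_meioses); enumerate all 2^r assignments of those bits with
# the rest frozen at 0 and tabulate the pair's shared-label count.
# Cached on the pedigree. States are identified with integers whose bit k
# is the (k+1)-th relevant meiosis in the frozen order.
ibd_model <- function(ped, max_bits = getOption("contibd.max_bits", 22L)) {
  if (!is.null(ped$cache$model)) return(ped$cache$model)
  rel <- ped$relevant
  r <- length(rel)
  if (r > max_bits) {
    capacity_error(paste0(
      "state space too large: ", r, " relevant meioses (2^", r,
      " states) exceeds the limit of ", max_bits,
      " bits; raise options(contibd.max_bits=) if this is intended"))
  }
  nv <- bitwShiftL(1L, r)
  states <- seq_len(nv) - 1L
  n <- length(ped$id)
  # per-member haplotype labels across all reduced states; scalars until a
  # relevant bit makes them state-dependent
  pat <- vector("list", n); mat <- vector("list", n)
  for (i in ped$founders) {
    pat[[i]] <- 2L * i - 1L
    mat[[i]] <- 2L * i
  }
  mrow <- ped$meioses
  bitpos <- match(seq_len(nrow(mrow)), rel)  # NA for irrelevant meioses
  for (j in ped$topo) {
    if (is.na(ped$father_idx[j])) next
    kp <- which(mrow$child == j & mrow$type == "paternal")
    km <- which(mrow$child == j & mrow$type == "maternal")
    f <- ped$father_idx[j]; m <- ped$mother_idx[j]
    pick <- function(k, p_pat, p_mat) {
      if (is.na(bitpos[k])) return(p_pat)            # frozen to 0
      bit <- bitwAnd(states, bitwShiftL(1L, bitpos[k] - 1L)) > 0L
      if (length(p_pat) == 1L && length(p_mat) == 1L) {
        ifelse(bit, p_mat, p_pat)
      } else {
        out <- rep(p_pat, length.out = nv)
        pm <- rep(p_mat, length.out = nv)
        out[bit] <- pm[bit]
        out
      }
    }
    pat[[j]] <- pick(kp, pat[[f]], mat[[f]])
    mat[[j]] <- pick(km, pat[[m]], mat[[m]])
  }
  a <- ped$pair[1]; b <- ped$pair[2]
  pa <- rep(pat[[a]], length.out = nv); ma <- rep(mat[[a]], length.out = nv)
  pb <- rep(pat[[b]], length.out = nv); mb <- rep(mat[[b]], length.out = nv)
  shared <- (pa == pb | pa == mb) + (ma == pb | ma == mb)
  model <- list(nbits = r, nv = nv,
                ibd1 = shared == 1L, ibd2 = shared == 2L,
                relevant = rel)
  ped$cache$model <- model
  model
}

#' Identity coefficients by exhaustive enumeration
#'
#' Computes the single-locus identity coefficients kappa0, kappa1, kappa2
#' for the pedigree pair by iterating over all equally probable IBD
#' vectors (after discarding meioses that provably cannot affect the
#' pair's IBD state, which keeps the enumeration exact but tractable for
#' distant relationships). Results are exact: the denominators are powers
#' of two, representable without rounding.
#'
#' @param ped an [ibd_pedigree()], abbreviation, or `relationship_spec`.
#' @return a list of class `identity_coefficients` with numeric `k0`,
#'   `k1`, `k2` and the exact fraction `k1_frac` as `c(numerator,
#'   log2_denominator)`.
#' @examples
#' identity_coefficients(relationship("GP"))$k1   # 1/2
#' identity_coefficients(relationship("5C"))$k1   # 1/1024
#' @export
identity_coefficients <- function(ped) {
  ped <- as_ibd_pedigree(ped)
  mod <- ibd_model(ped)
  n1 <- sum(mod$ibd1); n2 <- sum(mod$ibd2)
  structure(list(
    k0 = (mod$nv - n1 - n2) / mod$nv,
    k1 = n1 / mod$nv,
    k2 = n2 / mod$nv,
    k1_frac = c(n1, mod$nbits),
    nv = mod$nv
  ), class = "identity_coefficients")
}

#' @export
print.identity_coefficients <- function(x, ...) {
  frac <- function(num, logden) {
    den <- 2^logden
    if (num == 0) return("0")
    g <- 1
    while (num %% 2 == 0 && den > 1) { num <- num / 2; den <- den / 2 }
    if (den == 1) as.character(num) else paste0(num, "/", den)
  }
  cat("kappa0 =", format(x$k0), " kappa1 =",
      frac(x$k1_frac[1], x$k1_frac[2]),
      paste0("(", format(x$k1), ")"), " kappa2 =", format(x$k2), "\n")
  invisible(x)
}
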