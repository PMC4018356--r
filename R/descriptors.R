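# The 13-descriptor physicochemical panel.
#
# Count descriptors (MW, nHBDon, nHBAcc, N_rot, nRing, nAR, N_plus_O) are
# computed natively from the molecular graph. The continuous surface/partition
# models (AlogP, logD, logS, MPSA, MFPSA, MSA) go through a pluggable
# provider contract; the default provider implements simple additive
# approximations (Ertl-style polar-surface contributions, atom-contribution
# logP, an ESOL-style solubility regression). These stand-ins are monotone
# with the quantities they approximate and are documented as approximations;
# swap in a provider backed by a full cheminformatics toolkit for
# publication-grade values.

.DESCRIPTOR_NAMES <- c("AlogP", "logD", "logS", "MW", "nHBDon", "nHBAcc",
                       "N_rot", "nRing", "nAR", "N_plus_O", "MPSA", "MFPSA",
                       "MSA")

#' Compute the 13-descriptor panel for one molecule
#'
#' @param mol a standardized [molgraph].
#' @param provider a function `(mol, counts)` returning a named list with
#'   elements `AlogP`, `logD`, `logS`, `MPSA`, `MSA`; defaults to
#'   [default_descriptor_provider]. If the provider fails, its descriptors
#'   are returned as `NA` with a warning.
#' @return named numeric vector of the 13 descriptors.
#' @export
compute_descriptors <- function(mol, provider = default_descriptor_provider) {
  adj <- adjacency(mol)
  at <- mol$atoms
  n <- n_atoms(mol)
  deg <- lengths(lapply(adj, `[[`, "nbr"))

  mw <- sum(vapply(seq_len(n), function(i) {
    w <- .ATOMIC_WEIGHTS[at$symbol[i]]
    if (is.na(w)) w <- 0
    w + at$hcount[i] * .ATOMIC_WEIGHTS[["H"]]
  }, 0))

  is_NO <- at$symbol %in% c("N", "O")
  nhbdon <- sum(is_NO & at$hcount >= 1L)

  # acceptors: N/O excluding pyrrole-type N (aromatic, H-bearing) and amide N
  amide_n <- vapply(seq_len(n), function(i) {
    if (at$symbol[i] != "N") return(FALSE)
    for (t in seq_along(adj[[i]]$nbr)) {
      j <- adj[[i]]$nbr[t]
      if (adj[[i]]$order[t] == 1 && at$symbol[j] == "C") {
        jo <- adj[[j]]
        if (any(jo$order == 2 & at$symbol[jo$nbr] == "O")) return(TRUE)
      }
    }
    FALSE
  }, FALSE)
  pyrrole_n <- at$symbol == "N" & at$aromatic & at$hcount >= 1L
  nhbacc <- sum(is_NO & !(at$symbol == "N" & (amide_n | pyrrole_n)))

  rings <- sssr(mol)
  ring_bond <- ring_bond_flags(mol)
  nrot <- 0L
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$order[k] != 1 || ring_bond[k]) next
      if (deg[mol$bonds$a1[k]] >= 2L && deg[mol$bonds$a2[k]] >= 2L)
        nrot <- nrot + 1L
    }
  }
  nring <- length(rings)
  nar <- sum(vapply(rings, function(r) all(at$aromatic[r]), FALSE))
  npo <- sum(at$symbol %in% c("N", "O"))

  counts <- c(MW = mw, nHBDon = nhbdon, nHBAcc = nhbacc, N_rot = nrot,
              nRing = nring, nAR = nar, N_plus_O = npo)

  cont <- tryCatch(provider(mol, counts), error = function(e) {
    warning(sprintf("descriptor provider failed (%s); continuous descriptors set to NA",
                    conditionMessage(e)))
    list(AlogP = NA_real_, logD = NA_real_, logS = NA_real_,
         MPSA = NA_real_, MSA = NA_real_)
  })
  mpsa <- cont$MPSA; msa <- cont$MSA
  mfpsa <- if (!is.na(mpsa) && !is.na(msa) && msa > 0) mpsa / msa else NA_real_

  out <- c(AlogP = cont$AlogP, logD = cont$logD, logS = cont$logS, counts["MW"],
           counts["nHBDon"], counts["nHBAcc"], counts["N_rot"], counts["nRing"],
           counts["nAR"], counts["N_plus_O"], MPSA = mpsa, MFPSA = mfpsa,
           MSA = msa)
  names(out) <- .DESCRIPTOR_NAMES
  out
}

#' Default continuous-descriptor provider
#'
#' Additive approximations for the continuous members of the descriptor
#' panel. Polar surface area follows Ertl-style fragment contributions for
#' the common N/O/S environments; molecular surface area is an overlap-scaled
#' sum of van der Waals sphere areas; AlogP is a coarse atom-contribution
#' model; logD subtracts a unit penalty per formal charge; logS is an
#' ESOL-style linear model in AlogP, MW, rotatable bonds and aromatic
#' proportion.
#'
#' @param mol a [molgraph].
#' @param counts named vector of the count descriptors (from
#'   [compute_descriptors]).
#' @return named list with `AlogP`, `logD`, `logS`, `MPSA`, `MSA`.
#' @export
default_descriptor_provider <- function(mol, counts) {
  adj <- adjacency(mol)
  at <- mol$atoms
  n <- n_atoms(mol)

  tpsa <- 0
  for (i in seq_len(n)) {
    s <- at$symbol[i]; h <- at$hcount[i]; arom <- at$aromatic[i]
    ords <- adj[[i]]$order
    dbl <- sum(ords == 2); trp <- sum(ords == 3); deg_i <- length(ords)
    contrib <- 0
    if (s == "N") {
      contrib <- if (arom) {
        if (h >= 1L) 15.79 else if (deg_i >= 3L) 4.41 else 12.89
      } else if (trp > 0) 23.79
      else if (dbl > 0) { if (h >= 1L) 23.85 else 12.36 }
      else { if (h >= 2L) 26.02 else if (h == 1L) 12.03 else 3.24 }
      if (at$charge[i] > 0) contrib <- max(0, contrib - 10)
    } else if (s == "O") {
      contrib <- if (arom) 13.14
      else if (dbl > 0) 17.07
      else if (h >= 1L) 20.23
      else 9.23
      if (at$charge[i] < 0) contrib <- 23.06
    } else if (s == "S") {
      contrib <- if (arom) 28.24 else if (dbl > 0) 32.09 else 25.30
    } else if (s == "P") {
      contrib <- 13.59
    }
    tpsa <- tpsa + contrib
  }

  msa <- 0
  for (i in seq_len(n)) {
    r <- .VDW_RADII[at$symbol[i]]
    if (is.na(r)) r <- 1.7
    msa <- msa + 0.30 * 4 * pi * r^2 +
      at$hcount[i] * 0.30 * 4 * pi * .VDW_RADII[["H"]]^2
  }

  logp_contrib <- c(C_ar = 0.29, C_al = 0.12, N_ar = -0.25, N_al = -0.60,
                    O_ar = -0.15, O_al = -0.40, S = 0.40, P = -0.45,
                    F = 0.22, Cl = 0.65, Br = 0.88, I = 1.12)
  alogp <- 0
  for (i in seq_len(n)) {
    s <- at$symbol[i]
    key <- if (s %in% c("C", "N", "O"))
      paste0(s, if (at$aromatic[i]) "_ar" else "_al") else s
    v <- logp_contrib[key]
    if (is.na(v)) v <- 0
    alogp <- alogp + v
    if (s == "C") alogp <- alogp + 0.10 * at$hcount[i]
    if (s %in% c("N", "O")) alogp <- alogp - 0.10 * at$hcount[i]
  }
  logd <- alogp - 1.0 * sum(at$charge != 0)
  arom_prop <- mean(at$aromatic)
  logs <- 0.16 - 0.63 * alogp - 0.0062 * counts[["MW"]] +
    0.066 * counts[["N_rot"]] - 0.74 * arom_prop

  list(AlogP = alogp, logD = logd, logS = logs, MPSA = tpsa, MSA = msa)
}

#' Descriptor matrix for a list of records
#'
#' @param records list of `list(mol, activity)` entries.
#' @param provider continuous-descriptor provider, see [compute_descriptors].
#' @return numeric matrix (compounds x 13), rownames = compound ids.
#' @export
descriptor_matrix <- function(records, provider = default_descriptor_provider) {
  m <- t(vapply(records, function(r) compute_descriptors(r$mol, provider),
                numeric(length(.DESCRIPTOR_NAMES))))
  rownames(m) <- vapply(records, function(r) r$mol$id, "")
  m
}
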