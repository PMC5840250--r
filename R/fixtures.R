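#' Built-in hypothetical secondary-metabolite dataset
#'
#' A deterministic 13-sample x 13-compound dataset built to exercise every
#' contrast between biosynthetically informed and conventional distances:
#' five monoterpenes (MEP pathway, including alpha- and beta-pinene with
#' identical enzyme rows — one multi-product terpene synthase — and
#' beta-phellandrene differing from them only in its final enzyme), five
#' aromatics (shikimate pathway, including indole) and three fatty-acid
#' derivatives (LOX pathway). Each pathway shares a backbone of enzymes and
#' adds one terminal enzyme per compound, so within-pathway Sorensen
#' dissimilarities are small and cross-pathway ones are exactly 1.
#'
#' The profiles A-M are engineered so that, after standardization, the
#' biosynthetic distance is smaller than Bray-Curtis for the pairs (C,D)
#' (same two pathways, not a single shared compound), (E,F) (differ only in
#' alpha- vs beta-pinene), (G,H) (aromatics sharing one third of their
#' compounds) and all pairs among (I,J,K,L) (identical compound sets at
#' different quantities).
#'
#' @return a list with `samples` (13 x 13 quantity matrix), `enzymes`
#'   (compound x enzyme 0/1 matrix) and `classes` (compound x pathway-class
#'   0/1 matrix).
#' @export
make_hypothetical_dataset <- function() {
  mono <- c("alpha-pinene", "beta-pinene", "beta-phellandrene", "limonene", "myrcene")
  arom <- c("indole", "benzaldehyde", "methyl salicylate", "2-phenylethanol",
            "benzyl alcohol")
  fad <- c("(Z)-3-hexen-1-ol", "(Z)-3-hexenyl acetate", "hexanal")
  compounds <- c(mono, arom, fad)

  backbone <- list(
    mono = paste0("mep.", c("dxs", "dxr", "mct", "cmk", "mcs", "hds", "hdr", "gpps")),
    arom = paste0("shik.", c("dahps", "dhqs", "dhqd", "sdh", "epsps", "cs")),
    fad  = paste0("lox.", c("lox", "hpl", "isom"))
  )
  # one terminal enzyme per compound, except the pinenes: same synthase
  terminal <- c(
    "alpha-pinene" = "tps.pin", "beta-pinene" = "tps.pin",
    "beta-phellandrene" = "tps.phe", "limonene" = "tps.lim", "myrcene" = "tps.myr",
    "indole" = "igl", "benzaldehyde" = "pal.bza", "methyl salicylate" = "samt",
    "2-phenylethanol" = "aadc.pea", "benzyl alcohol" = "bzd.bzo",
    "(Z)-3-hexen-1-ol" = "adh.hxo", "(Z)-3-hexenyl acetate" = "aat.hxa",
    "hexanal" = "red.hxl")
  pathway_of <- c(rep("mono", 5), rep("arom", 5), rep("fad", 3))
  names(pathway_of) <- compounds

  enzymes_all <- c(unlist(backbone), unique(terminal))
  enzymes <- matrix(0, length(compounds), length(enzymes_all),
                    dimnames = list(compounds, enzymes_all))
  for (cmp in compounds) {
    enzymes[cmp, backbone[[pathway_of[cmp]]]] <- 1
    enzymes[cmp, terminal[cmp]] <- 1
  }

  classes <- matrix(0, length(compounds), 3,
                    dimnames = list(compounds,
                                    c("monoterpene", "aromatic", "fatty-acid derivative")))
  classes[cbind(compounds,
                c("monoterpene", "aromatic", "fatty-acid derivative")[
                  match(pathway_of, c("mono", "arom", "fad"))])] <- 1

  samples <- matrix(0, 13, length(compounds),
                    dimnames = list(LETTERS[1:13], compounds))
  put <- function(s, ...) {
    q <- c(...)
    samples[s, names(q)] <<- q
  }
  # A, B, M: single-pathway bouquets anchoring the pathway clades
  put("A", "alpha-pinene" = 40, "beta-phellandrene" = 10, "limonene" = 30, "myrcene" = 20)
  put("B", "benzaldehyde" = 40, "methyl salicylate" = 30, "2-phenylethanol" = 20,
      "benzyl alcohol" = 10)
  put("M", "(Z)-3-hexen-1-ol" = 30, "(Z)-3-hexenyl acetate" = 40, "hexanal" = 30)
  # C, D: same two pathways, not a single shared compound
  put("C", "alpha-pinene" = 60, "benzaldehyde" = 40)
  put("D", "limonene" = 60, "methyl salicylate" = 40)
  # E, F: differ only in alpha- vs beta-pinene (two thirds of compounds shared)
  put("E", "alpha-pinene" = 30, "(Z)-3-hexen-1-ol" = 40, "hexanal" = 30)
  put("F", "beta-pinene" = 30, "(Z)-3-hexen-1-ol" = 40, "hexanal" = 30)
  # G, H: all aromatic, sharing one third of their compounds
  put("G", "indole" = 40, "benzaldehyde" = 30, "2-phenylethanol" = 30)
  put("H", "indole" = 40, "methyl salicylate" = 30, "benzyl alcohol" = 30)
  # I, J, K, L: identical compound sets, quantities shuffled
  put("I", "alpha-pinene" = 70, "limonene" = 15, "benzaldehyde" = 15)
  put("J", "alpha-pinene" = 15, "limonene" = 70, "benzaldehyde" = 15)
  put("K", "alpha-pinene" = 45, "limonene" = 40, "benzaldehyde" = 15)
  put("L", "alpha-pinene" = 30, "limonene" = 55, "benzaldehyde" = 15)

  validate_sample_matrix(samples)
  validate_feature_matrix(enzymes)
  validate_feature_matrix(classes)
  list(samples = samples, enzymes = enzymes, classes = classes)
}

#' Simulate a two-species floral-scent dataset
#'
#' Emulates the structure of a floral volatile study comparing two plant
#' species: a 40-compound pool partitioned into 25 compounds exclusive to
#' species A, 4 exclusive to species B and 11 shared, monoterpene-dominated,
#' with `n_per_species` samples per species. Per-compound mean emissions are
#' drawn once, per-sample quantities log-normally around the species mean,
#' and each compound occurs in a sample with a per-compound occupancy
#' probability; every compound is forced to appear in at least one sample of
#' each species that emits it, so the exclusivity bookkeeping is exact by
#' construction. Fully reproducible given `seed`.
#'
#' @param seed integer seed.
#' @param n_per_species samples per species (>= 2).
#' @return a list with `samples` (2*`n_per_species` x 40 quantity matrix,
#'   rows `SpA_1..n`, `SpB_1..n`), `enzymes` (40-compound x enzyme 0/1
#'   matrix) and `species` (factor of length 2*`n_per_species`).
#' @export
make_two_species_dataset <- function(seed = 1, n_per_species = 9) {
  if (n_per_species < 2) stop("n_per_species must be >= 2")
  set.seed(seed)

  # pathway layout: monoterpene-dominated overall, but the exclusive pools
  # differ in pathway composition (species A carries a sesquiterpene block
  # the other species lacks, as an Asteraceae/Brassicaceae pair would)
  pathways <- c(rep("mep", 10), rep("mva", 6), rep("shik", 5), rep("lox", 4),  # A only
                rep("shik", 2), rep("lox", 2),                                 # B only
                rep("mep", 6), rep("shik", 3), rep("lox", 2))                  # shared
  ownership <- c(rep("A", 25), rep("B", 4), rep("AB", 11))
  compounds <- sprintf("cmpd%02d_%s", seq_len(40), pathways)

  backbone <- list(
    mep = paste0("mep.bb", 1:8), mva = paste0("mva.bb", 1:6),
    shik = paste0("shik.bb", 1:6), lox = paste0("lox.bb", 1:3))
  terminal <- paste0("term.", seq_len(40))
  # one multi-product synthase: first two shared-pool monoterpenes
  mep_shared <- which(pathways == "mep" & ownership == "AB")
  if (length(mep_shared) >= 2) terminal[mep_shared[2]] <- terminal[mep_shared[1]]

  enzymes_all <- c(unlist(backbone), unique(terminal))
  enzymes <- matrix(0, 40, length(enzymes_all),
                    dimnames = list(compounds, enzymes_all))
  for (i in seq_len(40)) {
    enzymes[i, backbone[[pathways[i]]]] <- 1
    enzymes[i, terminal[i]] <- 1
  }

  n <- 2 * n_per_species
  sample_ids <- c(sprintf("SpA_%d", seq_len(n_per_species)),
                  sprintf("SpB_%d", seq_len(n_per_species)))
  species <- factor(rep(c("A", "B"), each = n_per_species))

  # per-compound mean level: the shared monoterpenes dominate both bouquets,
  # and each species' characteristic exclusive block (the sesquiterpenes of
  # A, the few compounds only B emits) sits among its dominant compounds,
  # as species-diagnostic volatiles typically do
  marker <- (ownership == "A" & pathways == "mva") | ownership == "B" |
    (ownership == "AB" & pathways == "mep")
  mu <- stats::rlnorm(40, meanlog = 2 + 0.8 * marker, sdlog = 0.7)
  # occurrence probability rises with mean abundance: dominant compounds are
  # detected in every sample, trace compounds only sporadically
  occupancy <- 0.4 + 0.58 * (rank(mu) - 1) / 39
  emits <- function(sp, k) ownership[k] == "AB" || ownership[k] == sp

  samples <- matrix(0, n, 40, dimnames = list(sample_ids, compounds))
  for (s in seq_len(n)) {
    sp <- as.character(species[s])
    for (k in seq_len(40)) {
      if (emits(sp, k) && stats::runif(1) < occupancy[k])
        samples[s, k] <- stats::rlnorm(1, meanlog = log(mu[k]), sdlog = 0.8)
    }
  }
  # guarantee the designed ownership: each compound present in >= 1 sample
  # of every species that emits it
  for (k in seq_len(40)) {
    for (sp in c("A", "B")) {
      if (!emits(sp, k)) next
      rows <- which(species == sp)
      if (all(samples[rows, k] == 0)) {
        s <- sample(rows, 1)
        samples[s, k] <- stats::rlnorm(1, meanlog = log(mu[k]), sdlog = 0.8)
      }
    }
  }

  validate_sample_matrix(samples)
  validate_feature_matrix(enzymes)
  list(samples = samples, enzymes = enzymes, species = species)
}

#' Compound-sharing bookkeeping between two groups of samples
#'
#' Counts, over a sample x compound matrix split into two groups, how many
#' compounds occur only in the first group, only in the second, in both, and
#' in total — the numbers usually quoted when two species' bouquets are
#' compared.
#'
#' @param m sample x compound quantity matrix.
#' @param groups factor with two levels, one per sample.
#' @return a list with `total`, `exclusive` (named by group level) and
#'   `shared`.
#' @export
compound_bookkeeping <- function(m, groups) {
  validate_sample_matrix(m)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) stop("exactly two groups required")
  lv <- levels(droplevels(groups))
  in1 <- colSums(m[groups == lv[1], , drop = FALSE]) > 0
  in2 <- colSums(m[groups == lv[2], , drop = FALSE]) > 0
  detected <- in1 | in2
  excl <- c(sum(in1 & !in2), sum(in2 & !in1))
  names(excl) <- lv
  list(total = sum(detected), exclusive = excl, shared = sum(in1 & in2))
}
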