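#' Specification of a synthetic multi-omics dataset
#'
#' Describes a planted-block dataset emulating a small field survey: a
#' handful of sampling points, several groups ("types") of OTUs whose
#' abundances co-fluctuate with a dedicated subset of chemical variables,
#' plus uncorrelated OTUs, singleton OTUs and uncorrelated chemical
#' variables, with measurement noise throughout.  The defaults mirror the
#' survey design the pipeline was built around: 14 sampling points, 4
#' planted types of 25 OTUs and 5 chemical variables each, and noise
#' standard deviation 0.1 relative to the unit-variance latent factors.
#'
#' @param n_samples number of sampling points (default 14).
#' @param n_types number of planted association blocks (default 4).
#' @param otus_per_type member OTUs per block (default 25).
#' @param chems_per_type member chemical variables per block (default 5).
#' @param n_null_otus OTUs with no planted association (default 30).
#' @param n_singleton_otus OTUs carrying exactly one read in total
#'   (default 10); these exercise the singleton filter.
#' @param n_null_chems chemical variables with no planted association
#'   (default 6).
#' @param noise_sd Gaussian noise standard deviation added to the latent
#'   factor before the link function (default 0.1).
#' @param link `"linear"` or `"monotone_nonlinear"` mapping from latent
#'   factor to expected signal.
#' @param sequencing_depth multinomial reads per sample per domain
#'   (default 1e5).
#' @param seed RNG seed; the generator is fully deterministic given it.
#' @return a `bgc_synth_spec` list.
#' @export
bgc_synth_spec <- function(n_samples = 14L, n_types = 4L, otus_per_type = 25L,
                           chems_per_type = 5L, n_null_otus = 30L,
                           n_singleton_otus = 10L, n_null_chems = 6L,
                           noise_sd = 0.1,
                           link = c("linear", "monotone_nonlinear"),
                           sequencing_depth = 1e5, seed = 1L) {
  link <- match.arg(link)
  counts <- c(n_samples = n_samples, n_types = n_types,
              otus_per_type = otus_per_type, chems_per_type = chems_per_type,
              n_null_otus = n_null_otus, n_singleton_otus = n_singleton_otus,
              n_null_chems = n_null_chems)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("all counts must be non-negative integers")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_samples < 3) stop("need at least 3 sampling points")
  structure(list(n_samples = as.integer(n_samples),
                 n_types = as.integer(n_types),
                 otus_per_type = as.integer(otus_per_type),
                 chems_per_type = as.integer(chems_per_type),
                 n_null_otus = as.integer(n_null_otus),
                 n_singleton_otus = as.integer(n_singleton_otus),
                 n_null_chems = as.integer(n_null_chems),
                 noise_sd = noise_sd, link = link,
                 sequencing_depth = sequencing_depth,
                 seed = as.integer(seed)),
            class = "bgc_synth_spec")
}

# Monotone link from latent signal to a strictly positive expected intensity.
# The linear link offsets the signal far enough from zero that clipping is
# a measure-zero event; the nonlinear link is exponential.
apply_link <- function(z, link, base) {
  if (link == "linear") pmax(base + z, 1e-9) else exp(0.6 * z)
}

#' Generate a planted-block multi-omics dataset
#'
#' Draws one latent factor per planted type over the sampling points
#' (unit-variance simplex contrasts of a random orthonormal basis, so the
#' planted trends are genuinely distinct and sum to zero across types at
#' every sampling point).  Member OTU intensities and
#' member chemical values are monotone functions of their type's factor
#' plus Gaussian noise; null features are independent noise.  OTU counts
#' are drawn multinomially per sampling point at `sequencing_depth` within
#' each of the three amplicon domains (members are dealt round-robin to the
#' archaea/16S/18S tables, so types span domains); singleton OTUs are
#' appended with exactly one read at a random sampling point.  Chemical
#' variables are dealt round-robin to the icp/ftir/nmr platform tables.
#'
#' @param spec a [bgc_synth_spec()].
#' @return list with elements `community` (3 count [feature_table]s with
#'   taxonomy), `chemicals` (3 [feature_table]s), and `truth` — a list with
#'   `otu_types` and `chem_types` (named integer vectors over fused,
#'   block-prefixed ids; 0 marks null features, -1 singleton OTUs) and
#'   `factors` (types x samples latent matrix).
#' @export
generate_bgc_dataset <- function(spec = bgc_synth_spec()) {
  stopifnot(inherits(spec, "bgc_synth_spec"))
  domains <- c("archaea", "16S", "18S")
  platforms <- c("icp", "ftir", "nmr")
  kinds <- c(icp = "concentration_ppm", ftir = "integral", nmr = "integral")
  n_member <- spec$n_types * spec$otus_per_type
  otus_per_domain <- ceiling((n_member + spec$n_null_otus) / 3) + 1
  if (spec$sequencing_depth < 100 * otus_per_domain)
    stop("sequencing_depth too small to realize singleton OTUs reliably; ",
         "need >= ", 100 * otus_per_domain)
  with_seed(spec$seed, {
    samples <- sprintf("s%02d", seq_len(spec$n_samples))
    fac <- matrix(stats::rnorm(spec$n_types * spec$n_samples),
                  spec$n_types, spec$n_samples,
                  dimnames = list(NULL, samples))
    if (spec$n_types > 1 && spec$n_types <= spec$n_samples) {
      # With few sampling points, independently drawn factors carry large
      # chance correlations, so the planted blocks would not actually be
      # distinct.  Replace them by regular-simplex contrasts over an
      # orthonormalized random sample basis: factors keep unit population
      # variance, have pairwise correlation -1/(n_types - 1), and sum to
      # zero across types at every sampling point (so the per-sample read
      # total does not itself track any factor).
      k <- spec$n_types
      b <- qr.Q(qr(matrix(1, k, 1)), complete = TRUE)[, -1, drop = FALSE]
      tet <- b / sqrt(1 - 1 / k)               # unit simplex vertices
      q <- qr.Q(qr(t(fac)))[, seq_len(k - 1), drop = FALSE]
      fac <- tet %*% t(q) * sqrt(spec$n_samples)
      dimnames(fac) <- list(NULL, samples)
    }

    # community: member + null OTU intensities
    otu_type <- c(rep(seq_len(spec$n_types), each = spec$otus_per_type),
                  rep(0L, spec$n_null_otus))
    n_otu <- length(otu_type)
    inten <- matrix(0, n_otu, spec$n_samples)
    for (i in seq_len(n_otu)) {
      z <- if (otu_type[i] > 0)
        fac[otu_type[i], ] + stats::rnorm(spec$n_samples, 0, spec$noise_sd)
      else stats::rnorm(spec$n_samples)
      # amplitude 2 keeps the planted rank order well clear of the
      # multinomial sampling noise at the default depth
      inten[i, ] <- apply_link(2 * z, spec$link, base = 6)
    }
    otu_ids <- sprintf("otu%04d", seq_len(n_otu))
    dom_of <- domains[(seq_len(n_otu) - 1L) %% 3L + 1L]

    community <- list()
    truth_otu <- integer(0)
    for (d in domains) {
      idx <- which(dom_of == d)
      counts <- matrix(0, length(idx), spec$n_samples,
                       dimnames = list(otu_ids[idx], samples))
      for (s in seq_len(spec$n_samples)) {
        p <- inten[idx, s]
        counts[, s] <- stats::rmultinom(1, size = spec$sequencing_depth,
                                        prob = p / sum(p))[, 1]
      }
      # singletons: dealt round-robin over domains as well
      sing <- which(((seq_len(spec$n_singleton_otus) - 1L) %% 3L + 1L) ==
                      match(d, domains))
      if (length(sing)) {
        sm <- matrix(0, length(sing), spec$n_samples,
                     dimnames = list(sprintf("sing%03d", sing), samples))
        for (r in seq_along(sing))
          sm[r, sample.int(spec$n_samples, 1)] <- 1
        counts <- rbind(counts, sm)
      }
      tax <- lapply(rownames(counts), function(id) {
        i <- match(id, otu_ids)
        if (is.na(i)) c(paste0("Domain_", d), "Phylum_singleton")
        else if (otu_type[i] > 0)
          c(paste0("Domain_", d), paste0("Phylum_", otu_type[i]),
            paste0("Class_", otu_type[i]))
        else if (i %% 5 == 0)  # some null lineages stop at phylum
          c(paste0("Domain_", d), "Phylum_null")
        else c(paste0("Domain_", d), "Phylum_null", "Class_null")
      })
      names(tax) <- rownames(counts)
      community[[d]] <- feature_table(counts, block = d,
                                      value_kind = "counts", taxonomy = tax)
      tt <- c(otu_type[idx],
              rep(-1L, length(sing)))
      names(tt) <- paste(d, rownames(counts), sep = ":")
      truth_otu <- c(truth_otu, tt)
    }

    # chemicals: member + null variables
    chem_type <- c(rep(seq_len(spec$n_types), each = spec$chems_per_type),
                   rep(0L, spec$n_null_chems))
    n_chem <- length(chem_type)
    chem_ids <- sprintf("chem%03d", seq_len(n_chem))
    plat_of <- platforms[(seq_len(n_chem) - 1L) %% 3L + 1L]
    chem_vals <- matrix(0, n_chem, spec$n_samples,
                        dimnames = list(chem_ids, samples))
    for (j in seq_len(n_chem)) {
      z <- if (chem_type[j] > 0)
        fac[chem_type[j], ] + stats::rnorm(spec$n_samples, 0, spec$noise_sd)
      else stats::rnorm(spec$n_samples)
      chem_vals[j, ] <- apply_link(2 * z, spec$link, base = 10)
    }
    chemicals <- list()
    truth_chem <- integer(0)
    for (p in platforms) {
      idx <- which(plat_of == p)
      chemicals[[p]] <- feature_table(chem_vals[idx, , drop = FALSE],
                                      block = p, value_kind = kinds[[p]])
      tt <- chem_type[idx]
      names(tt) <- paste(p, chem_ids[idx], sep = ":")
      truth_chem <- c(truth_chem, tt)
    }

    list(community = community, chemicals = chemicals,
         truth = list(otu_types = truth_otu, chem_types = truth_chem,
                      factors = fac))
  })
}
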