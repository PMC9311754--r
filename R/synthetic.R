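#' Configuration for the synthetic PPI benchmark generator
#'
#' The generator emulates the structure the pipeline consumes: a
#' collection of variable-length N x 20 integer score matrices with
#' residue-profile structure, plus a planted latent-similarity
#' interaction signal of tunable strength. Proteins belong to latent
#' functional modules: each module has a latent direction (mutually
#' orthogonal, norm 3) and a protein's latent vector is its module
#' direction plus spherical noise, so latent alignment (inner product)
#' is high within modules and near zero across them. PSSM column means
#' are an affine function of the latent vector, and interacting pairs
#' are drawn preferentially among proteins with well-aligned latents.
#' `separation = 0` removes the signal entirely (labels independent of
#' the data, the null benchmark).
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer (min, max) residue counts; default 50-120,
#'   mirroring the conventional >= 50-residue benchmark filter.
#' @param latent_dim Dimension of the hidden latent vectors (default 12;
#'   must be >= `n_modules`).
#' @param n_modules Number of latent functional modules (default 12).
#' @param separation Signal strength >= 0 scaling the logistic
#'   positive-pair link (default 4).
#' @param n_pos_pairs,n_neg_pairs Numbers of interacting /
#'   non-interacting pairs to draw.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_proteins = 120L, length_range = c(50L, 120L),
                             latent_dim = 12L, n_modules = 12L,
                             separation = 4,
                             n_pos_pairs = 200L, n_neg_pairs = 200L,
                             seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              length_range = as.integer(length_range),
              latent_dim = as.integer(latent_dim),
              n_modules = as.integer(n_modules),
              separation = as.numeric(separation),
              n_pos_pairs = as.integer(n_pos_pairs),
              n_neg_pairs = as.integer(n_neg_pairs),
              seed = as.integer(seed))
  stopifnot(cfg$n_proteins >= 1L,
            length(cfg$length_range) == 2L,
            cfg$length_range[1] >= 1L,
            cfg$length_range[2] >= cfg$length_range[1],
            cfg$latent_dim >= 1L,
            cfg$n_modules >= 1L, cfg$n_modules <= cfg$latent_dim,
            cfg$separation >= 0,
            cfg$n_pos_pairs >= 1L, cfg$n_neg_pairs >= 1L)
  n_avail <- cfg$n_proteins * (cfg$n_proteins - 1L) / 2
  if (cfg$n_pos_pairs + cfg$n_neg_pairs > n_avail)
    stop("requested ", cfg$n_pos_pairs + cfg$n_neg_pairs,
         " pairs but only ", n_avail, " distinct unordered pairs exist",
         call. = FALSE)
  class(cfg) <- "synthetic_config"
  cfg
}

# score-generation constants: integer log-odds clipped to PSI-BLAST-like
# magnitudes, module-direction norm, within-module latent sd, column-mean
# tilt per unit latent, per-entry score noise sd
.SYN_CLIP <- c(-10, 12)
.SYN_CENTER_NORM <- 3
.SYN_WITHIN_SD <- 0.25
.SYN_TILT <- 2
.SYN_NOISE_SD <- 1

#' Generate synthetic proteins with latent-structured PSSMs
#'
#' Module directions are the first `n_modules` columns of a random
#' orthonormal basis of the latent space, scaled to norm 3; proteins are
#' assigned to modules round-robin and receive their module direction
#' plus spherical N(0, 0.25^2) noise as latent vector. A fixed random
#' 20 x latent_dim loading (columns scaled by `1/sqrt(latent_dim)`) maps
#' latents to per-column mean shifts of the score distribution, so
#' proteins with similar latents have similar PSSM column statistics.
#' Scores are integer, clipped to \[-10, 12\]. Sequences are the
#' per-position argmax column letter, so sequence and matrix are
#' mutually consistent. Fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param world_seed Seed for the shared generative "world" (module
#'   directions, residue loading, base score profile). Defaults to
#'   `config$seed`. Pass the seed of a training configuration to draw an
#'   independent protein collection from the same world — the synthetic
#'   analogue of a second species whose proteins follow the same
#'   sequence-to-interaction biology (used by the independent-test
#'   protocol).
#' @param id_prefix Prefix for generated protein ids (default `"syn"`).
#' @return List with `sequences` (named character vector), `pssms` (list
#'   of [pssm] objects), `latents` (n_proteins x latent_dim matrix,
#'   rownames = protein ids) and `modules` (integer module memberships).
#' @export
generate_proteins <- function(config, world_seed = NULL, id_prefix = "syn") {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(world_seed)) world_seed <- config$seed
  n <- config$n_proteins
  ld <- config$latent_dim
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  # world parameters: drawn from world_seed so several protein collections
  # can share one generative map
  set.seed(world_seed)
  basis <- qr.Q(qr(matrix(stats::rnorm(ld * ld), ld)))
  centers <- t(basis[, seq_len(config$n_modules), drop = FALSE]) *
    .SYN_CENTER_NORM
  loading <- matrix(stats::rnorm(20L * ld), 20L) / sqrt(ld)
  base_mu <- stats::rnorm(20L)
  # protein-level sampling: its own stream, offset from the pair stream
  set.seed(config$seed + 11L)
  modules <- rep_len(seq_len(config$n_modules), n)
  Z <- centers[modules, , drop = FALSE] +
    matrix(stats::rnorm(n * ld, sd = .SYN_WITHIN_SD), n, ld)
  dimnames(Z) <- list(ids, NULL)
  lens <- sample(seq(config$length_range[1], config$length_range[2]), n,
                 replace = TRUE)
  pssms <- vector("list", n)
  seqs <- character(n)
  for (p in seq_len(n)) {
    mu <- base_mu + .SYN_TILT * drop(loading %*% Z[p, ])
    raw <- matrix(stats::rnorm(lens[p] * 20L, mean = rep(mu, each = lens[p]),
                               sd = .SYN_NOISE_SD),
                  lens[p], 20L)
    scores <- pmin(pmax(round(raw), .SYN_CLIP[1]), .SYN_CLIP[2])
    pssms[[p]] <- pssm(ids[p], scores)
    seqs[p] <- paste0(AA_ORDER[max.col(scores, ties.method = "first")],
                      collapse = "")
    attr(pssms[[p]], "residues") <- seqs[p]
  }
  list(sequences = stats::setNames(seqs, ids), pssms = pssms, latents = Z,
       modules = modules)
}

#' Sample a labeled pair list with a planted interaction signal
#'
#' Positive (interacting) pairs are drawn without replacement from all
#' distinct unordered pairs with a shifted logistic sampling weight
#' \deqn{w_{ab} = \mathrm{plogis}\big(\mathrm{separation} \cdot
#'   (\langle z_a, z_b\rangle - \tau) / \sigma\big)}
#' where \eqn{\tau} is the 95th percentile of inner products over all
#' pairs and \eqn{\sigma} their median absolute deviation, so
#' interaction probability increases with latent alignment and, at
#' moderate separation, concentrates on the aligned (same-module) tail.
#' Negative pairs are drawn uniformly from the remaining pairs. With
#' `separation = 0` every weight is 0.5, both draws are uniform, and
#' labels carry no signal.
#'
#' @param latents Latent matrix from [generate_proteins()] (rownames =
#'   ids).
#' @param config The same [synthetic_config()].
#' @return Data.frame `id_a`, `id_b`, `label`, positives first.
#' @export
generate_pairs <- function(latents, config) {
  stopifnot(inherits(config, "synthetic_config"),
            nrow(latents) == config$n_proteins)
  set.seed(config$seed + 1L)
  ids <- rownames(latents)
  n <- nrow(latents)
  comb <- utils::combn(n, 2L)
  n_avail <- ncol(comb)
  if (config$n_pos_pairs + config$n_neg_pairs > n_avail)
    stop("requested more pairs than available", call. = FALSE)
  ip <- rowSums(latents[comb[1, ], , drop = FALSE] *
                latents[comb[2, ], , drop = FALSE])
  tau <- stats::quantile(ip, 0.95, names = FALSE)
  sig <- stats::mad(ip)
  if (!is.finite(sig) || sig <= 0) sig <- 1
  w <- stats::plogis(config$separation * (ip - tau) / sig)
  pos <- sample.int(n_avail, config$n_pos_pairs, prob = w)
  rest <- setdiff(seq_len(n_avail), pos)
  neg <- rest[sample.int(length(rest), config$n_neg_pairs)]
  sel <- c(pos, neg)
  data.frame(id_a = ids[comb[1, sel]],
             id_b = ids[comb[2, sel]],
             label = rep(c(1L, 0L), c(config$n_pos_pairs, config$n_neg_pairs)),
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic benchmark in memory
#'
#' Convenience wrapper running [generate_proteins()] and
#' [generate_pairs()] from one config. Passing a training
#' configuration's seed as `world_seed` (with a different
#' `config$seed`) yields an independent dataset from the same
#' generative world, suitable for the cross-dataset test protocol.
#'
#' @param config A [synthetic_config()].
#' @param world_seed,id_prefix Passed to [generate_proteins()].
#' @return List with `sequences`, `pssms`, `latents`, `modules`,
#'   `pairs`, `config`.
#' @export
simulate_ppi_data <- function(config = synthetic_config(),
                              world_seed = NULL, id_prefix = "syn") {
  prot <- generate_proteins(config, world_seed = world_seed,
                            id_prefix = id_prefix)
  pairs <- generate_pairs(prot$latents, config)
  c(prot, list(pairs = pairs, config = config))
}

#' Write a synthetic benchmark to disk in the standard formats
#'
#' Writes a multi-record FASTA, one PSI-BLAST-style ASCII PSSM file per
#' protein, the labeled pair list as TSV, and a JSON manifest recording
#' the file names and generating configuration. Everything written is
#' read back by the `pssm_io` readers, so on-disk fixtures and in-memory
#' objects round-trip.
#'
#' @param dir Output directory (created if needed).
#' @param data Result of [simulate_ppi_data()].
#' @return Path of the manifest file, invisibly.
#' @export
write_fixture <- function(dir, data) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pssm_dir <- file.path(dir, "pssm")
  dir.create(pssm_dir, showWarnings = FALSE)
  write_fasta(data$sequences, file.path(dir, "proteins.fasta"))
  pssm_files <- character(length(data$pssms))
  for (i in seq_along(data$pssms)) {
    id <- data$pssms[[i]]$protein_id
    pssm_files[i] <- file.path("pssm", paste0(id, ".pssm"))
    write_ascii_pssm(data$pssms[[i]], file.path(dir, pssm_files[i]))
  }
  write_pair_list(data$pairs, file.path(dir, "pairs.tsv"))
  manifest <- list(fasta = "proteins.fasta",
                   pssm_files = pssm_files,
                   pairs = "pairs.tsv",
                   config = unclass(data$config))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest_path)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir Fixture directory containing `manifest.json`.
#' @return List with `sequences`, `pssms`, `pairs`, `config`.
#' @export
read_fixture <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath))
    stop("not a fixture directory (no manifest.json): ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  seqs <- read_fasta(file.path(dir, manifest$fasta))
  pssms <- lapply(file.path(dir, manifest$pssm_files), read_ascii_pssm)
  pairs <- read_pair_list(file.path(dir, manifest$pairs),
                          ids = vapply(pssms, `[[`, "", "protein_id"))
  list(sequences = seqs, pssms = pssms, pairs = pairs,
       config = manifest$config)
}
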