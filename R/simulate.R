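#' Configuration for the synthetic dataset generator
#'
#' The generator plants the structure the prediction pipeline is built to
#' detect: per-GO-term coexpression modules driven by latent sample factors,
#' domain-function associations for a fraction of terms, and isoforms that
#' inherit or lose their gene's expression signal and domains. Defaults
#' describe the package's reference in-silico study condition.
#'
#' @param n_genes number of genes. Default 2000.
#' @param n_samples number of samples. Default 300.
#' @param n_terms number of GO terms. Default 60.
#' @param term_size integer range (inclusive) of annotated genes per term.
#'   Default `c(15, 40)`.
#' @param n_domains number of protein domains. Default 120.
#' @param rho_signal loading of an annotated gene's latent expression on its
#'   term's sample factor, in `[0, 1]`. Default 0.5. With the default
#'   `noise_sd`, two genes sharing a term have latent correlation
#'   `rho_signal^2`.
#' @param noise_sd standard deviation of the independent latent noise;
#'   `NULL` (default) gives `sqrt(1 - rho_signal^2)` so latent variance is 1.
#' @param frac_informative fraction of terms that get dedicated predictive
#'   domains. Default 0.4.
#' @param domains_per_term dedicated domains per informative term. Default 2.
#' @param domain_tpr probability an annotated gene carries each of its
#'   term's dedicated domains. Default 0.9.
#' @param domain_fpr probability a non-annotated gene carries such a domain.
#'   Default 0.02.
#' @param background_rate presence probability of non-dedicated (background)
#'   domains in any gene. Default 0.05.
#' @param iso_rate isoform count per gene is `1 + Poisson(iso_rate)`.
#'   Default 2.
#' @param principal_fidelity probability the principal isoform keeps the
#'   gene's expression signal (constant splicing usage). Default 0.9.
#' @param usage_noise_sd lognormal sd of the sample-varying splicing usage
#'   of unfaithful isoforms (larger = more decorrelated from the gene).
#'   Default 1.
#' @param domain_drop_prob probability an alternative isoform drops each of
#'   its gene's domains. Default 0.3. The principal isoform keeps all
#'   domains, so the gene's domain set equals the union over isoforms.
#' @param seed integer seed; every draw flows from it.
#' @return object of class `simulation_config` (validated list).
#' @export
simulation_config <- function(n_genes = 2000L, n_samples = 300L,
                              n_terms = 60L, term_size = c(15L, 40L),
                              n_domains = 120L, rho_signal = 0.5,
                              noise_sd = NULL, frac_informative = 0.4,
                              domains_per_term = 2L, domain_tpr = 0.9,
                              domain_fpr = 0.02, background_rate = 0.05,
                              iso_rate = 2, principal_fidelity = 0.9,
                              usage_noise_sd = 1, domain_drop_prob = 0.3,
                              seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    n_terms = as.integer(n_terms), term_size = as.integer(term_size),
    n_domains = as.integer(n_domains), rho_signal = rho_signal,
    noise_sd = noise_sd %||% sqrt(max(0, 1 - rho_signal^2)),
    frac_informative = frac_informative,
    domains_per_term = as.integer(domains_per_term),
    domain_tpr = domain_tpr, domain_fpr = domain_fpr,
    background_rate = background_rate, iso_rate = iso_rate,
    principal_fidelity = principal_fidelity,
    usage_noise_sd = usage_noise_sd, domain_drop_prob = domain_drop_prob,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(n_genes > 0, n_samples > 0, n_terms > 0, n_domains >= 0,
              length(term_size) == 2, term_size[1] <= term_size[2],
              term_size[1] >= 1, rho_signal >= 0, rho_signal <= 1,
              noise_sd >= 0, frac_informative >= 0, frac_informative <= 1,
              domain_tpr >= 0, domain_tpr <= 1, domain_fpr >= 0,
              domain_fpr <= 1, principal_fidelity >= 0,
              principal_fidelity <= 1, domain_drop_prob >= 0,
              domain_drop_prob <= 1)
  })
  if (cfg$term_size[2] > cfg$n_genes) {
    stopf("term sizes up to %d are infeasible with %d genes",
          cfg$term_size[2], cfg$n_genes)
  }
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d genes x %d samples, %d terms [%d-%d], %d domains, rho = %s, seed %d\n",
    x$n_genes, x$n_samples, x$n_terms, x$term_size[1], x$term_size[2],
    x$n_domains, format(x$rho_signal), x$seed
  ))
  invisible(x)
}

#' Simulate a full synthetic dataset
#'
#' Generates expression, annotations, domains and isoform structure from a
#' latent-factor model. Each term has a latent Gaussian sample factor; genes
#' annotated to a term load on it with `rho_signal` (genes in several terms
#' load on the normalized sum of their factors), plus independent Gaussian
#' noise, so within-term pairs have closed-form latent correlation
#' `rho_signal^2 / (rho_signal^2 + noise_sd^2)`. Latent expression maps to
#' TPM through a strictly increasing softplus link with per-gene shift and
#' scale, which leaves rank statistics untouched. Genes split their TPM
#' among isoforms by Dirichlet usage shares: faithful isoforms keep constant
#' shares (so they are rank-identical to their gene); unfaithful ones get
#' sample-varying lognormal usage noise, decorrelating them. Isoform rows
#' sum exactly to the gene row, so [aggregate_gene_expression()] inverts the
#' split. Dedicated domains are planted in informative terms' genes at the
#' configured true/false positive rates; alternative isoforms drop domains
#' at random, the principal keeps all.
#'
#' @param cfg a [simulation_config()].
#' @return list with `iso_expr`, `gene_expr` (TPM matrices), `annotations`
#'   (gene-level [annotation_set()] with ontology labels), `gene_domains`,
#'   `iso_domains` ([domain_annotation()]), `map` (isoform map tibble),
#'   `truth` (tibble: which isoform truly carries each annotated function),
#'   `informative_terms`, `term_domains`, and `config`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(cfg$seed, simulate_dataset_impl(cfg))
}

simulate_dataset_impl <- function(cfg) {
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  samples <- sprintf("S%04d", seq_len(cfg$n_samples))
  terms <- sprintf("T%03d", seq_len(cfg$n_terms))
  domains <- if (cfg$n_domains > 0) sprintf("D%04d", seq_len(cfg$n_domains))
             else character(0)

  # term membership
  sizes <- sample(seq(cfg$term_size[1], cfg$term_size[2]), cfg$n_terms,
                  replace = TRUE)
  members <- lapply(sizes, function(k) sample(genes, k))
  ann_pairs <- data.frame(
    entity_id = unlist(members),
    term_id = rep(terms, times = sizes)
  )
  ontology <- sample(c("BP", "MF", "CC"), cfg$n_terms, replace = TRUE,
                     prob = c(0.759, 0.153, 0.088))
  ann <- annotation_set(
    cbind(ann_pairs, ontology = ontology[match(ann_pairs$term_id, terms)]),
    entities = genes, terms = terms
  )

  # latent expression: term factors + per-gene loadings
  factors <- matrix(rnorm(cfg$n_terms * cfg$n_samples), cfg$n_terms,
                    dimnames = list(terms, samples))
  terms_of <- lapply(seq_along(genes), function(i) {
    which(vapply(members, function(m) genes[i] %in% m, logical(1)))
  })
  latent <- matrix(rnorm(cfg$n_genes * cfg$n_samples), cfg$n_genes,
                   dimnames = list(genes, samples))
  for (i in seq_along(genes)) {
    tg <- terms_of[[i]]
    if (length(tg) > 0) {
      sig <- colSums(factors[tg, , drop = FALSE]) / sqrt(length(tg))
      latent[i, ] <- cfg$rho_signal * sig + cfg$noise_sd * latent[i, ]
    }
  }
  shift <- rnorm(cfg$n_genes, 1, 1)
  size <- exp(rnorm(cfg$n_genes, 1, 1))
  gene_expr <- softplus(latent + shift) * size
  dimnames(gene_expr) <- list(genes, samples)

  # domains
  n_inf <- min(round(cfg$frac_informative * cfg$n_terms),
               if (cfg$domains_per_term > 0 && cfg$n_domains > 0)
                 cfg$n_domains %/% cfg$domains_per_term else 0)
  informative <- if (n_inf > 0) sort(sample(terms, n_inf)) else character(0)
  dom_m <- matrix(0, cfg$n_genes, cfg$n_domains,
                  dimnames = list(genes, domains))
  term_domains <- list()
  d_next <- 1L
  for (t in informative) {
    dd <- domains[seq(d_next, d_next + cfg$domains_per_term - 1L)]
    d_next <- d_next + cfg$domains_per_term
    term_domains[[t]] <- dd
    in_term <- genes %in% members[[match(t, terms)]]
    for (d in dd) {
      p <- ifelse(in_term, cfg$domain_tpr, cfg$domain_fpr)
      dom_m[, d] <- pmax(dom_m[, d], rbinom(cfg$n_genes, 1, p))
    }
  }
  if (d_next <= cfg$n_domains) {
    bg <- domains[seq(d_next, cfg$n_domains)]
    dom_m[, bg] <- matrix(rbinom(cfg$n_genes * length(bg), 1,
                                 cfg$background_rate),
                          cfg$n_genes)
  }
  gene_dom <- new_domain_annotation(methods::as(Matrix::Matrix(
    dom_m, sparse = TRUE), "CsparseMatrix"))

  # isoforms: Dirichlet usage, principal = largest share
  n_iso <- 1L + rpois(cfg$n_genes, cfg$iso_rate)
  iso_ids <- unlist(lapply(seq_along(genes), function(i) {
    paste0(genes[i], ".", seq_len(n_iso[i]))
  }))
  iso_gene <- rep(genes, times = n_iso)
  principal <- unlist(lapply(n_iso, function(k) c(TRUE, rep(FALSE, k - 1L))))
  faithful <- logical(length(iso_ids))
  iso_expr <- matrix(0, length(iso_ids), cfg$n_samples,
                     dimnames = list(iso_ids, samples))
  iso_dom_m <- matrix(0, length(iso_ids), cfg$n_domains,
                      dimnames = list(iso_ids, domains))
  row0 <- 0L
  for (i in seq_along(genes)) {
    k <- n_iso[i]
    rows <- row0 + seq_len(k)
    row0 <- row0 + k
    share <- sort(rgamma(k, 1), decreasing = TRUE)
    share <- share / sum(share)
    faith <- c(runif(1) < cfg$principal_fidelity, rep(FALSE, k - 1L))
    if (k == 1L) faith <- TRUE
    faithful[rows] <- faith
    # faithful isoforms keep constant usage (exactly proportional to the
    # gene); unfaithful ones split the remaining usage with sample-varying
    # lognormal weights, so only they decorrelate
    w <- matrix(share, k, cfg$n_samples)
    noisy <- !faith
    if (any(noisy)) {
      wn <- w[noisy, , drop = FALSE] *
        exp(matrix(rnorm(sum(noisy) * cfg$n_samples, 0, cfg$usage_noise_sd),
                   sum(noisy)))
      wn <- sweep(wn, 2L, colSums(wn), `/`) * sum(share[noisy])
      w[noisy, ] <- wn
    }
    iso_expr[rows, ] <- w * rep(gene_expr[i, ], each = k)
    # principal keeps every gene domain; alternatives drop at random
    gd <- dom_m[i, ]
    iso_dom_m[rows[1L], ] <- gd
    if (k > 1L) {
      present <- which(gd > 0)
      for (r in rows[-1L]) {
        keep <- present[runif(length(present)) >= cfg$domain_drop_prob]
        iso_dom_m[r, keep] <- 1
      }
    }
  }
  map <- tibble::tibble(isoform_id = iso_ids, gene_id = iso_gene,
                        principal = principal)

  # truth: which isoforms truly carry each annotated function
  truth <- dplyr::bind_rows(lapply(seq_along(terms), function(j) {
    t <- terms[j]
    gset <- members[[j]]
    rows <- which(iso_gene %in% gset)
    if (length(rows) == 0) return(NULL)
    dd <- term_domains[[t]]
    keeps_domains <- if (is.null(dd)) rep(TRUE, length(rows)) else {
      apply(iso_dom_m[rows, dd, drop = FALSE] ==
              dom_m[iso_gene[rows], dd, drop = FALSE], 1L, all)
    }
    tibble::tibble(
      isoform_id = iso_ids[rows], gene_id = iso_gene[rows], term_id = t,
      faithful_expression = faithful[rows],
      keeps_term_domains = unname(keeps_domains),
      carries_function = faithful[rows] & unname(keeps_domains)
    )
  }))

  list(
    iso_expr = iso_expr,
    gene_expr = gene_expr,
    annotations = ann,
    gene_domains = gene_dom,
    iso_domains = new_domain_annotation(methods::as(Matrix::Matrix(
      iso_dom_m, sparse = TRUE), "CsparseMatrix")),
    map = map,
    truth = truth,
    informative_terms = informative,
    term_domains = term_domains,
    config = cfg
  )
}
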