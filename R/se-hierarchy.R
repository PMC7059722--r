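## Super-enhancer hierarchy: H-score, gamma-fit hub calling, hierarchical SE
## classification, SE interaction taxonomy and SE-gene distances.

#' H-score of constituent enhancers within a super-enhancer
#'
#' For enhancer i in a super-enhancer with s constituents, the H-score is the
#' PET count EN(i) normalized by the enhancer peak size L(i) and the mean PET
#' count of the SE's constituents: H(i) = EN(i) / (L(i) * mean(EN)). A large
#' H-score marks an enhancer whose interactions are disproportionately
#' enriched relative to its SE siblings.
#'
#' @param EN PET counts per constituent enhancer (one SE).
#' @param L peak sizes per enhancer, in kilobases (so H-scores are O(1)).
#'   Hub calling is invariant to a global rescaling of all L.
#' @return numeric H-scores; all zero (with a warning) when mean(EN) is 0.
#' @examples
#' h_score(c(10, 20, 30), c(1, 1, 1))  # 0.5 1.0 1.5
#' @export
h_score <- function(EN, L) {
  if (length(EN) != length(L)) stop("EN and L must have the same length")
  if (any(L <= 0)) stop("L must be positive")
  m <- mean(EN)
  if (m == 0) {
    warning("all EN zero; H-scores set to 0")
    return(rep(0, length(EN)))
  }
  EN / (L * m)
}

#' Call hub enhancers by a gamma fit to pooled H-scores
#'
#' H-scores of all enhancers (pooled across SEs) are fitted as a gamma
#' distribution; each enhancer is assigned the upper-tail probability
#' P(H >= h), and enhancers with P < alpha are hub enhancers. Zero H-scores
#' are excluded from the fit and are never hubs.
#'
#' @param enhancers data.frame with columns `enhancer_id`, `se_id`, `EN`,
#'   `L` (kb); or with a precomputed `H` column.
#' @param alpha upper-tail significance level (default 0.05).
#' @param method gamma fit: `"mle"` (maximum likelihood, default) or
#'   `"moments"`.
#' @param min_positive minimum number of positive H-scores required for a
#'   stable fit (default 20).
#' @return list: `enhancers` (input plus H, p_value, hub) and `fit`
#'   (class `gamma_null`: shape, rate, alpha, method).
#' @export
call_hubs <- function(enhancers, alpha = 0.05,
                      method = c("mle", "moments"), min_positive = 20L) {
  method <- match.arg(method)
  df <- enhancers
  if (is.null(df$H)) {
    sp <- split(seq_len(nrow(df)), df$se_id)
    H <- numeric(nrow(df))
    for (idx in sp) H[idx] <- h_score(df$EN[idx], df$L[idx])
    df$H <- H
  }
  pos <- df$H[df$H > 0]
  if (length(pos) < min_positive)
    stop(sprintf("only %d positive H-scores (< %d); too few for a gamma fit",
                 length(pos), min_positive))
  if (stats::sd(pos) == 0 || length(unique(df$H)) == 1L) {
    warning("all H-scores equal; no hubs called")
    df$p_value <- 1
    df$hub <- FALSE
    fit <- structure(list(shape = NA_real_, rate = NA_real_, alpha = alpha,
                          method = method), class = "gamma_null")
    return(list(enhancers = df, fit = fit))
  }
  if (method == "mle") {
    est <- suppressWarnings(MASS::fitdistr(pos, "gamma"))$estimate
    shape <- est[["shape"]]; rate <- est[["rate"]]
  } else {
    m <- mean(pos); v <- stats::var(pos)
    shape <- m^2 / v; rate <- m / v
  }
  df$p_value <- ifelse(df$H > 0,
                       stats::pgamma(df$H, shape = shape, rate = rate,
                                     lower.tail = FALSE), 1)
  df$hub <- df$p_value < alpha & df$H > 0
  fit <- structure(list(shape = shape, rate = rate, alpha = alpha,
                        method = method, n_fit = length(pos)),
                   class = "gamma_null")
  list(enhancers = df, fit = fit)
}

#' @export
print.gamma_null <- function(x, ...) {
  cat(sprintf("Gamma null (%s fit): shape = %.4g, rate = %.4g, alpha = %g\n",
              x$method, x$shape, x$rate, x$alpha))
  invisible(x)
}

#' Classify super-enhancers as hierarchical or non-hierarchical
#'
#' A super-enhancer containing at least one hub enhancer is hierarchical.
#'
#' @param enhancers annotated enhancer data.frame from [call_hubs()] (needs
#'   `se_id` and `hub`).
#' @return data.frame: se_id, n_enhancers, n_hubs, hierarchical.
#' @export
classify_hierarchical <- function(enhancers) {
  sp <- split(enhancers$hub, enhancers$se_id)
  data.frame(se_id = names(sp),
             n_enhancers = lengths(sp),
             n_hubs = vapply(sp, sum, 0L),
             hierarchical = vapply(sp, any, NA),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Categorize SE interactions as SE-P, SE-G or SE-O
#'
#' Each call's partner region is labeled SE-P when it overlaps a promoter
#' window (TSS +/- `promoter_window`), else SE-G when it overlaps a gene
#' body, else SE-O (other genomic regions). Precedence SE-P > SE-G > SE-O;
#' each call gets exactly one label.
#'
#' @param calls calls data.frame (needs chrom, start, end).
#' @param genes gene-model data.frame from [read_gene_models()].
#' @param promoter_window half-width of the promoter window in bp
#'   (default 2000).
#' @return character vector of labels parallel to `calls`.
#' @export
categorize_se_interactions <- function(calls, genes, promoter_window = 2000L) {
  part <- GRanges(calls$chrom, IRanges(calls$start, calls$end))
  prom <- GRanges(genes$chrom,
                  IRanges(pmax(genes$tss - promoter_window, 1),
                          genes$tss + promoter_window))
  body <- GRanges(genes$chrom, IRanges(genes$start, genes$end))
  lab <- rep("SE-O", length(part))
  lab[overlapsAny(part, body, ignore.strand = TRUE)] <- "SE-G"
  lab[overlapsAny(part, prom, ignore.strand = TRUE)] <- "SE-P"
  lab
}

#' Map significant calls to SE-gene links
#'
#' A gene is linked to an SE when the SE has a high-confidence call whose
#' partner region overlaps the gene's promoter window.
#'
#' @param calls calls data.frame with `bait_id` giving the SE (or enhancer)
#'   id, `significant`/`high_confidence`, coordinates, `x` and `bf`.
#' @param genes gene models.
#' @param promoter_window promoter half-width bp.
#' @param se_of optional named vector mapping bait_id to SE id (identity when
#'   calls are already SE-level).
#' @return data.frame of links: se_id, gene_id, tss, enhancer mid, x, bf.
#' @export
se_gene_links <- function(calls, genes, promoter_window = 2000L,
                          se_of = NULL) {
  sig <- calls[calls$high_confidence, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(se_id = character(), gene_id = character(),
                      tss = numeric(), mid = numeric(), x = integer(),
                      bf = numeric(), stringsAsFactors = FALSE))
  part <- GRanges(sig$chrom, IRanges(sig$start, sig$end))
  prom <- GRanges(genes$chrom,
                  IRanges(pmax(genes$tss - promoter_window, 1),
                          genes$tss + promoter_window))
  hits <- findOverlaps(part, prom, ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(data.frame(se_id = character(), gene_id = character(),
                      tss = numeric(), mid = numeric(), x = integer(),
                      bf = numeric(), stringsAsFactors = FALSE))
  qi <- queryHits(hits); si <- subjectHits(hits)
  se_id <- sig$bait_id[qi]
  if (!is.null(se_of)) se_id <- unname(se_of[se_id])
  data.frame(se_id = se_id, gene_id = genes$gene_id[si],
             tss = genes$tss[si],
             mid = floor((sig$start[qi] + sig$end[qi]) / 2),
             x = sig$x[qi], bf = sig$bf[qi], stringsAsFactors = FALSE)
}

#' Classify SE-gene interaction patterns
#'
#' Builds the bipartite SE-gene graph from significant links and labels each
#' connected component: single SE to single gene, single SE to multiple
#' genes, multiple SEs to single gene, multiple SEs to multiple genes; SEs
#' absent from the graph are "no significant interacting gene".
#'
#' @param links SE-gene link data.frame from [se_gene_links()].
#' @param all_se_ids character vector of every SE id (so unlinked SEs are
#'   labeled too).
#' @return data.frame: se_id, pattern, component.
#' @export
classify_se_gene_patterns <- function(links, all_se_ids) {
  out <- data.frame(se_id = all_se_ids,
                    pattern = "no significant interacting gene",
                    component = NA_integer_, stringsAsFactors = FALSE)
  lk <- unique(links[c("se_id", "gene_id")])
  if (nrow(lk) > 0L) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = paste0("SE::", lk$se_id),
                 to = paste0("G::", lk$gene_id)), directed = FALSE)
    comp <- igraph::components(g)
    memb <- comp$membership
    vs <- names(memb)
    for (k in seq_len(comp$no)) {
      v <- vs[memb == k]
      ses <- sub("^SE::", "", v[startsWith(v, "SE::")])
      ngene <- sum(startsWith(v, "G::"))
      lab <- if (length(ses) == 1L && ngene == 1L) "single SE to single gene"
      else if (length(ses) == 1L) "single SE to multiple genes"
      else if (ngene == 1L) "multiple SEs to single gene"
      else "multiple SEs to multiple genes"
      sel <- out$se_id %in% ses
      out$pattern[sel] <- lab
      out$component[sel] <- k
    }
  }
  out
}

#' Distance from each interacting gene to its strongest enhancer
#'
#' For every gene linked to a super-enhancer, the distance is measured from
#' the gene TSS to the midpoint of the member enhancer with the strongest
#' interaction (highest PET count; ties broken by higher Bayes factor, then
#' leftmost midpoint).
#'
#' @param links SE-gene link data.frame (se_id, gene_id, tss, mid, x, bf).
#' @return data.frame: se_id, gene_id, distance (bp), mid, x, bf of the
#'   selected enhancer.
#' @export
se_gene_distance <- function(links) {
  if (nrow(links) == 0L)
    return(data.frame(se_id = character(), gene_id = character(),
                      distance = numeric(), mid = numeric(), x = integer(),
                      bf = numeric(), stringsAsFactors = FALSE))
  key <- paste(links$se_id, links$gene_id, sep = "\r")
  ord <- order(key, -links$x, -links$bf, links$mid)
  lk <- links[ord, , drop = FALSE]
  lk <- lk[!duplicated(paste(lk$se_id, lk$gene_id, sep = "\r")), , drop = FALSE]
  data.frame(se_id = lk$se_id, gene_id = lk$gene_id,
             distance = abs(lk$tss - lk$mid), mid = lk$mid, x = lk$x,
             bf = lk$bf, row.names = NULL, stringsAsFactors = FALSE)
}
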