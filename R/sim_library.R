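#' Generate a synthetic naive VHH library
#'
#' Draws `n_clones` distinct VHH clones: CDR1/2/3 amino-acid loops sampled
#' from the package's loop composition with CDR3 lengths following the
#' configured length law (median 18 aa, support 1-36), threaded between the
#' scaffold frameworks; one fixed synonymous-codon realization per clone
#' (so distinct nucleotide clonotypes can share an amino-acid clonotype
#' after sequencing error or codon collapse); lognormal initial frequencies
#' normalized to 1; and `n_binders_per_subtype` planted binders per sorted
#' subtype with lognormal affinity multipliers. A planted binder's capture
#' weight is elevated both in its target subtype and in the bulk CD45 pool
#' (which physically contains the target cells), so selection can compound
#' across rounds.
#'
#' @param config A [simulation_config()].
#' @return An object of class `vhh_library`: list with `clones` (data frame:
#'   `clone_id`, `cdr1_aa`, `cdr2_aa`, `cdr3_aa`, `aa`, `nt_cds`,
#'   `initial_freq`), `affinity` (clones x subtypes matrix), `binders`
#'   (data frame: `clone_id`, `subtype`, `kappa`), and the config.
#' @export
#' @examples
#' lib <- generate_library(simulation_config(n_clones = 50,
#'                                           n_binders_per_subtype = 2,
#'                                           seed = 1))
#' head(lib$clones$cdr3_aa)
generate_library <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  withr::with_seed(derive_seed(config$seed, "library"), {
    n <- config$n_clones
    comp <- cdr_aa_composition()
    sc <- config$scaffold

    draw_cdrs <- function() {
      l3 <- sample(as.integer(names(config$cdr3_length_law)), n,
                   replace = TRUE, prob = config$cdr3_length_law)
      l1 <- sample(seq(config$cdr1_length_range[1],
                       config$cdr1_length_range[2]), n, replace = TRUE)
      l2 <- sample(seq(config$cdr2_length_range[1],
                       config$cdr2_length_range[2]), n, replace = TRUE)
      list(cdr1 = random_peptides(l1, comp),
           cdr2 = random_peptides(l2, comp),
           cdr3 = random_peptides(l3, comp))
    }

    cdrs <- draw_cdrs()
    # enforce distinct clones at the amino-acid level
    for (iter in 1:20) {
      key <- paste(cdrs$cdr1, cdrs$cdr2, cdrs$cdr3)
      dup <- duplicated(key)
      if (!any(dup)) break
      redo <- draw_cdrs()
      cdrs$cdr1[dup] <- redo$cdr1[dup]
      cdrs$cdr2[dup] <- redo$cdr2[dup]
      cdrs$cdr3[dup] <- redo$cdr3[dup]
    }

    aa <- paste0(sc$fr1, cdrs$cdr1, sc$fr2, cdrs$cdr2, sc$fr3, cdrs$cdr3,
                 sc$fr4)
    nt <- encode_codons(aa)

    freq <- rlnorm(n, config$abundance_law[["meanlog"]],
                   config$abundance_law[["sdlog"]])
    freq <- freq / sum(freq)

    clone_id <- sprintf("clone%06d", seq_len(n))
    subtypes <- config$subtypes
    selectable <- subtypes[-1]
    bulk <- subtypes[1]
    affinity <- matrix(config$background_affinity, nrow = n,
                       ncol = length(subtypes),
                       dimnames = list(clone_id, subtypes))
    nb <- config$n_binders_per_subtype
    binders <- data.frame(clone_id = character(0), subtype = character(0),
                          kappa = numeric(0))
    if (nb > 0) {
      if (config$shared_binders) {
        picks <- lapply(selectable, function(s) sample.int(n, nb))
      } else {
        pool <- sample.int(n, nb * length(selectable))
        picks <- split(pool, rep(seq_along(selectable), each = nb))
      }
      for (k in seq_along(selectable)) {
        idx <- picks[[k]]
        kappa <- rlnorm(nb, config$affinity_law[["meanlog"]],
                        config$affinity_law[["sdlog"]])
        affinity[idx, selectable[k]] <-
          pmax(affinity[idx, selectable[k]], kappa)
        affinity[idx, bulk] <- pmax(affinity[idx, bulk], kappa)
        binders <- rbind(binders,
                         data.frame(clone_id = clone_id[idx],
                                    subtype = selectable[k], kappa = kappa))
      }
    }

    structure(
      list(clones = data.frame(clone_id = clone_id,
                               cdr1_aa = cdrs$cdr1, cdr2_aa = cdrs$cdr2,
                               cdr3_aa = cdrs$cdr3, aa = aa, nt_cds = nt,
                               initial_freq = freq,
                               stringsAsFactors = FALSE),
           affinity = affinity, binders = binders, config = config),
      class = "vhh_library")
  })
}

# sample `lengths[i]`-long peptides from a residue composition, vectorized
random_peptides <- function(lengths, composition) {
  total <- sum(lengths)
  if (total == 0) return(rep("", length(lengths)))
  chars <- sample(names(composition), total, replace = TRUE,
                  prob = composition)
  big <- paste(chars, collapse = "")
  ends <- cumsum(lengths)
  substring(big, ends - lengths + 1, ends)
}

# reverse-translate amino-acid strings with per-position uniform synonymous
# codon choice (fixed per clone)
encode_codons <- function(aa) {
  choices <- codon_choices()
  lens <- nchar(aa)
  ch <- strsplit(paste(aa, collapse = ""), "")[[1]]
  codons <- character(length(ch))
  for (a in unique(ch)) {
    idx <- which(ch == a)
    opts <- choices[[a]]
    codons[idx] <- opts[sample.int(length(opts), length(idx), replace = TRUE)]
  }
  big <- paste(codons, collapse = "")
  ends <- cumsum(3L * lens)
  substring(big, ends - 3L * lens + 1, ends)
}

#' @export
print.vhh_library <- function(x, ...) {
  cat(sprintf("VHH library: %d clones, %d planted binders\n",
              nrow(x$clones), nrow(x$binders)))
  cat(sprintf("  CDR3 length: median %d, range %d-%d\n",
              as.integer(median(nchar(x$clones$cdr3_aa))),
              min(nchar(x$clones$cdr3_aa)), max(nchar(x$clones$cdr3_aa))))
  invisible(x)
}
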