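# broom-style tidy()/glance() methods for the package's result objects.

#' @export
tidy.pwm <- function(x, ...) {
  tidyr::expand_grid(position = seq_len(ncol(x$prob)),
                     base = DNA_BASES) |>
    mutate(probability = x$prob[cbind(match(.data$base, DNA_BASES),
                                      .data$position)])
}

#' @export
glance.pwm <- function(x, ...) {
  ic <- apply(x$prob, 2, function(p) 2 + sum(p * log2(p)))
  tibble(
    width = ncol(x$prob),
    consensus = pwm_consensus(x),
    information_bits = sum(ic),
    pseudocount = x$pseudocount
  )
}

#' @export
tidy.methyl_motif <- function(x, ...) {
  freq <- x$counts / x$n_sites
  tidyr::expand_grid(position = seq_len(ncol(x$counts)),
                     base = rownames(x$counts)) |>
    mutate(
      count = x$counts[cbind(match(.data$base, rownames(x$counts)),
                             .data$position)],
      frequency = freq[cbind(match(.data$base, rownames(x$counts)),
                             .data$position)]
    )
}

#' @export
glance.methyl_motif <- function(x, ...) {
  ef <- methyl_motif_e_fraction(x)
  tibble(
    width = ncol(x$counts),
    n_sites = x$n_sites,
    n_e = sum(x$counts["E", ]),
    max_e_fraction = if (all(is.na(ef))) NA_real_ else max(ef, na.rm = TRUE)
  )
}

#' @export
tidy.methylation_profile <- function(x, ...) {
  tibble(offset = x$offset, mean_level = x$mean_level, n_cpg = x$n_cpg)
}

#' @export
glance.methylation_profile <- function(x, ...) {
  tibble(
    flank_bp = attr(x, "flank"),
    bin_bp = attr(x, "bin"),
    n_sites = attr(x, "n_sites"),
    n_contributions = sum(x$n_cpg)
  )
}
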