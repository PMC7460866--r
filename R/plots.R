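# ggplot2 views of the main result types

#' Plot an accumulation profile
#'
#' Bar chart of variants/Mb per interval (bands or chromosomes); the
#' `"unassigned"` tally is dropped.
#'
#' @param profile Output of [accumulate()] or [chromosome_profile()].
#' @return A ggplot object.
#' @export
plot_accumulation <- function(profile) {
  d <- filter(profile, is.na(.data$name) | .data$name != "unassigned")
  x <- if ("name" %in% names(d)) paste(d$chrom, d$name) else d$chrom
  ggplot(mutate(d, x = factor(x, levels = unique(x))),
         aes(x = .data$x, y = .data$per_mb)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "variants / Mb") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
}

#' Plot a substitution spectrum with Ti/Tv annotations
#'
#' @param titv_tbl Output of [titv()].
#' @return A ggplot object.
#' @export
plot_titv <- function(titv_tbl) {
  classes <- c("C>T", "C>A", "C>G", "T>A", "T>C", "T>G")
  d <- titv_tbl |>
    pivot_longer(dplyr::all_of(classes), names_to = "class",
                 values_to = "n") |>
    mutate(kind = ifelse(.data$class %in% c("C>T", "T>C"),
                         "transition", "transversion"))
  ggplot(d, aes(x = .data$class, y = .data$n, fill = .data$kind)) +
    geom_col() +
    facet_wrap(~group) +
    scale_fill_manual(values = c(transition = "firebrick",
                                 transversion = "grey40")) +
    labs(x = NULL, y = "SNV count", fill = NULL) +
    theme_minimal()
}

#' Plot an InDel signature spectrum
#'
#' @param spectrum Output of [indel_spectrum()].
#' @return A ggplot object.
#' @export
plot_indel_spectrum <- function(spectrum) {
  d <- mutate(spectrum,
              category = factor(.data$category, levels = .data$category),
              panel = paste(.data$indel_type, .data$context_class))
  ggplot(d, aes(x = .data$sub_length, y = .data$n,
                fill = .data$context_class)) +
    geom_col() +
    facet_grid(. ~ factor(panel, levels = unique(panel)),
               scales = "free_x", space = "free_x") +
    labs(x = "InDel length / biggest microhomology length",
         y = "InDel count", fill = "context") +
    theme_minimal() +
    theme(legend.position = "bottom")
}

#' Heatmap of binned variant counts across TADs and gaps
#'
#' @param profile Output of [tad_bin_profile()].
#' @return A ggplot object.
#' @export
plot_tad_profile <- function(profile) {
  ggplot(profile, aes(x = .data$bin, y = .data$domain_id,
                      fill = .data$count)) +
    geom_tile() +
    facet_grid(location ~ chrom, scales = "free_y", space = "free_y") +
    scale_fill_gradientn(colours = c("white", "orange", "red", "purple4")) +
    scale_x_continuous(breaks = seq_len(max(profile$bin))) +
    labs(x = "bin", y = NULL, fill = "variants") +
    theme_minimal()
}

#' Heatmap of translocation counts per chromosome pair
#'
#' @param matrix_tbl Output of [pair_matrix()].
#' @return A ggplot object.
#' @export
plot_translocation_matrix <- function(matrix_tbl) {
  sym <- bind_rows(
    matrix_tbl,
    matrix_tbl |> rename(chrom_a = "chrom_b", chrom_b = "chrom_a")
  )
  ggplot(sym, aes(x = .data$chrom_a, y = .data$chrom_b, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n), size = 3) +
    scale_fill_gradient(low = "white", high = "firebrick") +
    labs(x = NULL, y = NULL, fill = "events") +
    theme_minimal()
}
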