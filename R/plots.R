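utils::globalVariables(c("ratio", "chr", "quadrant", "m", "d"))

#' Thomas-plot scatter of classified panels
#'
#' sTfR/log10(ferritin) index against reticulocyte hemoglobin content, with
#' the CHr cut-off and the CRP-dependent ratio cut-off drawn as quadrant
#' boundaries. Points are coloured by assigned quadrant. When the input
#' mixes both CRP regimes the vertical cut-off is drawn at each distinct
#' value present.
#'
#' @param thomas a [classify_thomas()] result.
#' @param config a [pbm_config()].
#' @return A ggplot object.
#' @export
plot_thomas <- function(thomas, config = pbm_config()) {
  df <- as.data.frame(thomas)
  ggplot2::ggplot(df, ggplot2::aes(x = ratio, y = chr, colour = quadrant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = config$chr_cutoff,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = unique(df$ratio_cutoff),
                        linetype = "dashed") +
    ggplot2::labs(x = "sTfR / log10(ferritin)",
                  y = "CHr (pg)", colour = "Quadrant",
                  title = "Thomas plot") +
    ggplot2::theme_minimal()
}
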