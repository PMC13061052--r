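# Report emission: the per-modality metric table, the comparison table with
# significance (*) and power (**) markers, and the four standard plot types
# (ECG snippet, tachogram with epoch shading, Poincare scatter with SD1/SD2
# ellipse, banded PSD) plus the normalized-HR violin.

utils::globalVariables(c("time_ms", "signal", "channel", "rr_ms", "x", "y",
                         "freq", "power", "condition", "nhr", "modality"))

saveBoth <- function(plot, out_dir, stem, width = 7, height = 4.5) {
  paths <- file.path(out_dir, paste0(stem, c(".png", ".svg")))
  ggplot2::ggsave(paths[1], plot, width = width, height = height, dpi = 120)
  # grDevices::svg, not svglite, so no extra dependency is needed
  ggplot2::ggsave(paths[2], plot, device = grDevices::svg,
                  width = width, height = height)
  paths
}

epochShading <- function(schedule) {
  if (is.null(schedule)) return(NULL)
  e <- epochs(schedule)
  e$fill <- ifelse(e$label == "stimulation", "#d7301f55", "#2b8cbe33")
  ggplot2::geom_rect(data = e,
    ggplot2::aes(xmin = start_ms / 1000, xmax = end_ms / 1000,
                 ymin = -Inf, ymax = Inf),
    fill = e$fill, inherit.aes = FALSE)
}

pooledConditionRR <- function(rr, schedule) {
  segs <- segmentEpochs(rr, schedule)
  out <- list()
  for (cond in c("stimulation", "washout")) {
    sel <- segs[vapply(segs, function(s) s$epoch == cond, logical(1))]
    if (!length(sel)) next
    iv <- unlist(lapply(sel, function(s) validNN(s$rr)))
    out[[cond]] <- iv
  }
  out
}

#' Write the analysis report: tables and figures
#'
#' Emits, under \code{out_dir}:
#' \itemize{
#'   \item \code{metrics_table.csv} — metrics x modalities, per-epoch
#'     summaries averaged per modality (blank cells for undefined metrics);
#'   \item \code{comparisons_table.csv} — one row per metric with the
#'     modality-agreement p, the sequential S-W delta, Cohen's d and p, a
#'     \code{significant} column marked \code{*} exactly when p < 0.05 and a
#'     \code{powerful} column marked \code{**} when d > 0.5;
#'   \item \code{snippet.(png|svg)} — a 5-second dual-trace ECG snippet;
#'   \item \code{tachogram.(png|svg)} — full-session RR trend with epoch
#'     shading;
#'   \item \code{poincare.(png|svg)} and \code{poincare_ellipses.csv} —
#'     per-condition Poincare scatter with the SD1/SD2 ellipse, and the
#'     ellipse axes actually drawn;
#'   \item \code{psd.(png|svg)} — per-condition power spectral density with
#'     LF/HF band shading;
#'   \item \code{violin.(png|svg)} — normalized HR (per-beat instantaneous HR
#'     divided by the session mean of its modality) per modality and
#'     condition.
#' }
#'
#' @param summaries per-epoch [HRVSummary-class] list (all modalities) or a
#'   [summariesTable()] data.frame.
#' @param rr named list of session [RRSeries-class] per modality (used for
#'   the tachogram, Poincare, PSD and violin panels).
#' @param record optional [ECGRecord-class] for the snippet panel.
#' @param schedule optional [EpochSchedule-class] for epoch shading and
#'   condition pooling.
#' @param out_dir output directory, created if needed.
#' @param comparisons optional precomputed comparison table; when omitted it
#'   is assembled from \code{summaries} ([modalityAgreement()] across the
#'   two modalities and [sequentialAnalysis()] per modality).
#' @param lf_band,hf_band band edges (Hz) used for PSD shading.
#' @return Invisibly, the character vector of files written.
#' @export
buildReport <- function(summaries, rr = NULL, record = NULL, schedule = NULL,
                        out_dir, comparisons = NULL,
                        lf_band = c(0.2, 0.75), hf_band = c(0.75, 3)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  df <- asSummariesDF(summaries)
  lab <- hrvMetricLabels()
  written <- character(0)

  # (i) metrics x modalities table, per-epoch values averaged per modality
  mods <- unique(df$modality)
  tab1 <- data.frame(metric = unname(lab[hrvMetricNames()]))
  for (md in mods) {
    sub <- df[df$modality == md, hrvMetricNames(), drop = FALSE]
    tab1[[md]] <- vapply(hrvMetricNames(), function(k) {
      v <- sub[[k]][!is.na(sub[[k]])]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  p1 <- file.path(out_dir, "metrics_table.csv")
  utils::write.csv(tab1, p1, row.names = FALSE, na = "")
  written <- c(written, p1)

  # (ii) comparison table with significance and power markers
  if (is.null(comparisons)) {
    seq_tabs <- lapply(mods, function(md) {
      ss <- df[df$modality == md, , drop = FALSE]
      out <- tryCatch(sequentialAnalysis(ss), error = function(e) {
        message(sprintf("sequential analysis (%s) skipped: %s", md,
                        conditionMessage(e)))
        NULL
      })
      if (!is.null(out)) out$modality <- md
      out
    })
    comparisons <- do.call(rbind, seq_tabs)
    if (is.null(comparisons))
      comparisons <- data.frame(metric = character(0), kind = character(0),
                                mean_delta = numeric(0), cohens_d = numeric(0),
                                p_value = numeric(0), n_pairs = integer(0),
                                power_label = character(0))
    if (length(mods) == 2 && nrow(comparisons)) {
      agr <- modalityAgreement(df[df$modality == mods[1], , drop = FALSE],
                               df[df$modality == mods[2], , drop = FALSE])
      comparisons <- merge(comparisons,
                           data.frame(metric = agr$metric,
                                      agreement_p = agr$p_value),
                           by = "metric", all.x = TRUE, sort = FALSE)
    }
  }
  comparisons$significant <- ifelse(!is.na(comparisons$p_value) &
                                      comparisons$p_value < 0.05, "*", "")
  comparisons$powerful <- ifelse(!is.na(comparisons$cohens_d) &
                                   comparisons$cohens_d > 0.5, "**", "")
  p2 <- file.path(out_dir, "comparisons_table.csv")
  utils::write.csv(comparisons, p2, row.names = FALSE, na = "")
  written <- c(written, p2)

  # (iii) 5-second dual-trace snippet
  if (!is.null(record)) {
    fs <- sampleRate(record)
    n5 <- min(nrow(record@signals), round(5 * fs))
    snip <- do.call(rbind, lapply(channelLabels(record), function(ch)
      data.frame(time_ms = sampleTimes(record)[seq_len(n5)],
                 signal = channelSignal(record, ch)[seq_len(n5)],
                 channel = ch)))
    g <- ggplot2::ggplot(snip, ggplot2::aes(time_ms / 1000, signal)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
      ggplot2::labs(x = "time (s)", y = "normalized amplitude",
                    title = "ECG snippet (5 s)") +
      ggplot2::theme_minimal()
    written <- c(written, saveBoth(g, out_dir, "snippet", height = 6))
  }

  if (!is.null(rr) && length(rr)) {
    # (iv) tachogram with epoch shading
    tach <- do.call(rbind, lapply(names(rr), function(md) {
      s <- rr[[md]]
      data.frame(time_ms = beatTimes(s)[-1][rrValid(s)],
                 rr_ms = validNN(s), modality = md)
    }))
    g <- ggplot2::ggplot(tach, ggplot2::aes(time_ms / 1000, rr_ms,
                                            colour = modality)) +
      epochShading(schedule) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::labs(x = "time (s)", y = "RR (ms)",
                    title = "Tachogram (shaded: stimulation / washout)") +
      ggplot2::theme_minimal()
    written <- c(written, saveBoth(g, out_dir, "tachogram"))

    md1 <- names(rr)[1]
    conds <- if (is.null(schedule)) list() else
      pooledConditionRR(rr[[md1]], schedule)

    # (v) Poincare scatter with SD1/SD2 ellipse, per condition
    if (length(conds)) {
      pts <- do.call(rbind, lapply(names(conds), function(cn) {
        iv <- conds[[cn]]
        if (length(iv) < 3) return(NULL)
        data.frame(x = iv[-length(iv)], y = iv[-1], condition = cn)
      }))
      ell <- do.call(rbind, lapply(names(conds), function(cn) {
        iv <- conds[[cn]]
        pc <- poincare(rrSeries(cumsum(c(0, iv))))
        if (anyNA(pc[c("sd1", "sd2")])) return(NULL)
        th <- seq(0, 2 * pi, length.out = 181)
        mu <- mean(iv)
        # major axis (sd2) along the identity line, minor (sd1) across it
        data.frame(
          x = mu + (pc["sd2"] * cos(th) - pc["sd1"] * sin(th)) / sqrt(2),
          y = mu + (pc["sd2"] * cos(th) + pc["sd1"] * sin(th)) / sqrt(2),
          condition = cn)
      }))
      ell_tab <- do.call(rbind, lapply(names(conds), function(cn) {
        pc <- poincare(rrSeries(cumsum(c(0, conds[[cn]]))))
        data.frame(condition = cn, sd1 = pc[["sd1"]], sd2 = pc[["sd2"]])
      }))
      p3 <- file.path(out_dir, "poincare_ellipses.csv")
      utils::write.csv(ell_tab, p3, row.names = FALSE, na = "")
      written <- c(written, p3)
      g <- ggplot2::ggplot(pts, ggplot2::aes(x, y, colour = condition)) +
        ggplot2::geom_point(size = 0.5, alpha = 0.5) +
        { if (!is.null(ell))
            ggplot2::geom_path(data = ell, linewidth = 0.7) } +
        ggplot2::coord_equal() +
        ggplot2::labs(x = "NN[i] (ms)", y = "NN[i+1] (ms)",
                      title = sprintf("Poincare plot (%s)", md1)) +
        ggplot2::theme_minimal()
      written <- c(written, saveBoth(g, out_dir, "poincare", height = 5.5))
    }

    # (vi) per-condition PSD with band shading
    if (length(conds)) {
      psds <- do.call(rbind, lapply(names(conds), function(cn) {
        iv <- conds[[cn]]
        sp <- spectralPower(rrSeries(cumsum(c(0, iv))),
                            lf_band = lf_band, hf_band = hf_band)
        if (is.null(sp$psd)) return(NULL)
        cbind(sp$psd, condition = cn)
      }))
      if (!is.null(psds) && nrow(psds)) {
        bands <- data.frame(xmin = c(lf_band[1], hf_band[1]),
                            xmax = c(lf_band[2], hf_band[2]),
                            band = c("LF", "HF"))
        g <- ggplot2::ggplot(psds, ggplot2::aes(freq, power,
                                                colour = condition)) +
          ggplot2::geom_rect(data = bands,
            ggplot2::aes(xmin = xmin, xmax = xmax, ymin = -Inf, ymax = Inf),
            fill = c("#fee8c822", "#e0f3db22"), inherit.aes = FALSE) +
          ggplot2::geom_line() +
          ggplot2::coord_cartesian(xlim = c(0, hf_band[2] * 1.2)) +
          ggplot2::labs(x = "frequency (Hz)", y = "PSD (ms^2/Hz)",
                        title = sprintf("Tachogram PSD (%s)", md1)) +
          ggplot2::theme_minimal()
        written <- c(written, saveBoth(g, out_dir, "psd"))
      }
    }

    # (vii) normalized HR violin per modality and condition
    if (!is.null(schedule)) {
      vio <- do.call(rbind, lapply(names(rr), function(md) {
        conds_md <- pooledConditionRR(rr[[md]], schedule)
        base_hr <- mean(60000 / validNN(rr[[md]]))
        do.call(rbind, lapply(names(conds_md), function(cn)
          data.frame(nhr = (60000 / conds_md[[cn]]) / base_hr,
                     condition = cn, modality = md)))
      }))
      if (!is.null(vio) && nrow(vio)) {
        g <- ggplot2::ggplot(vio, ggplot2::aes(modality, nhr,
                                               fill = modality)) +
          ggplot2::geom_violin(linewidth = 0.3) +
          ggplot2::facet_wrap(~condition) +
          ggplot2::labs(x = NULL, y = "normalized HR",
                        title = "Normalized HR by modality and condition") +
          ggplot2::theme_minimal()
        written <- c(written, saveBoth(g, out_dir, "violin"))
      }
    }
  }
  invisible(written)
}
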