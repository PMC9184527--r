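## Scenario-conditional QTL allelic effects and favorable-allele
## frequency shifts between breeding eras.

.scenario_levels <- c("cool_WW", "warm_WW", "hot_WW",
                      "cool_WD", "warm_WD", "hot_WD")

#' QTL scenario-specific allelic-effect table
#'
#' One row per QTL: the peak marker, the QTL class (`adaptive` = effect
#' depends on the environmental scenario, `constitutive` = essentially
#' stable), the favorable allele (the allele with a positive yield effect
#' in the cool/well-watered scenario), and the allelic effect
#' (t ha-1 per favorable-allele copy) in each of the six scenarios.
#'
#' @param qtl QTL identifiers.
#' @param marker peak marker ids.
#' @param class `"adaptive"` or `"constitutive"` per QTL.
#' @param favorable_allele allele label (matched against the marker map's
#'   ref/alt).
#' @param effects matrix/data frame of effects with one column per
#'   scenario label (`cool_WW`, `warm_WW`, `hot_WW`, `cool_WD`,
#'   `warm_WD`, `hot_WD`).
#' @return Data frame of class `effect_table`.
#' @export
effect_table <- function(qtl, marker, class, favorable_allele, effects) {
  effects <- as.data.frame(effects)
  .assert(all(.scenario_levels %in% names(effects)),
          "effects must have columns %s",
          paste(.scenario_levels, collapse = ", "))
  .assert(all(class %in% c("adaptive", "constitutive")),
          "class must be 'adaptive' or 'constitutive'")
  .assert(all(vapply(effects[.scenario_levels],
                     function(x) all(is.finite(x)), logical(1))),
          "effects must be finite")
  out <- data.frame(qtl = as.character(qtl), marker = as.character(marker),
                    class = class, favorable_allele = favorable_allele,
                    effects[.scenario_levels], stringsAsFactors = FALSE)
  .assert(!anyDuplicated(out$qtl), "QTL ids must be unique")
  class(out) <- c("effect_table", class(out))
  out
}

#' Read / write an effect table as CSV
#' @param path CSV path.
#' @return An [effect_table()] (`read_effect_table`); `path` invisibly
#'   (`write_effect_table`).
#' @export
read_effect_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  effect_table(tab$qtl, tab$marker, tab$class, tab$favorable_allele,
               tab[.scenario_levels])
}

#' @rdname read_effect_table
#' @param x an [effect_table()].
#' @export
write_effect_table <- function(x, path) {
  stopifnot(inherits(x, "effect_table"))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Predict per-field allelic effects from scenario assignments
#'
#' Pure lookup: each field's predicted allelic effect for a QTL is the
#' effect estimated in that field's environmental scenario; per-QTL
#' summaries (min, max, mean, SD over fields) quantify how stable the
#' effect is across the multi-site experiment.
#'
#' @param effects an [effect_table()].
#' @param field_scenarios data frame with columns `experiment` and
#'   `scenario` (e.g. from [assign_scenario()]), or a named character
#'   vector of scenario labels indexed by field.
#' @return List with `per_field` (long data frame `qtl`, `experiment`,
#'   `scenario`, `effect`) and `summary` (`qtl`, `class`, `min`, `max`,
#'   `mean`, `sd`).
#' @export
predict_field_effects <- function(effects, field_scenarios) {
  stopifnot(inherits(effects, "effect_table"))
  if (is.data.frame(field_scenarios)) {
    scen <- stats::setNames(as.character(field_scenarios$scenario),
                            field_scenarios$experiment)
  } else {
    scen <- field_scenarios
  }
  bad <- setdiff(unique(scen), .scenario_levels)
  .assert(length(bad) == 0, "unknown scenario label(s): %s",
          paste(bad, collapse = ", "))
  per_field <- do.call(rbind, lapply(seq_len(nrow(effects)), function(i) {
    eff <- unlist(effects[i, .scenario_levels])
    .assert(!anyNA(eff[scen]), "missing effect for QTL %s in scenario %s",
            effects$qtl[i], paste(unique(scen[is.na(eff[scen])]),
                                  collapse = ", "))
    data.frame(qtl = effects$qtl[i], experiment = names(scen),
               scenario = unname(scen), effect = unname(eff[scen]),
               stringsAsFactors = FALSE)
  }))
  summary <- do.call(rbind, lapply(split(per_field, per_field$qtl),
                                   function(d) {
    data.frame(qtl = d$qtl[1],
               class = effects$class[match(d$qtl[1], effects$qtl)],
               min = min(d$effect), max = max(d$effect),
               mean = mean(d$effect), sd = stats::sd(d$effect),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(per_field = per_field, summary = summary)
}

#' Favorable-allele frequency shift between oldest and most recent hybrids
#'
#' Frequencies of each QTL's favorable allele in the `n_group` oldest and
#' `n_group` most recent hybrids (stable sort on year of release, ties
#' broken by hybrid id), computed over non-missing calls at the peak
#' marker. QTLs whose peak marker is absent are flagged with `NA` rather
#' than failing.
#'
#' @param G a [genotype_matrix()].
#' @param effects an [effect_table()].
#' @param meta data frame with columns `hybrid` and `year`.
#' @param n_group group size (default 22, the study design).
#' @return Data frame: `qtl`, `marker`, `class`, `freq_old`,
#'   `freq_recent`, `delta` (`recent - old`), `missing_marker`.
#' @export
favorable_freq_shift <- function(G, effects, meta, n_group = 22) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(effects, "effect_table"))
  .assert(all(c("hybrid", "year") %in% names(meta)),
          "meta needs 'hybrid' and 'year' columns")
  .assert(2 * n_group <= nrow(meta), "groups larger than the panel")
  ord <- order(meta$year, meta$hybrid)
  old_ids <- meta$hybrid[ord][seq_len(n_group)]
  rec_ids <- meta$hybrid[rev(ord)][seq_len(n_group)]
  oi <- match(old_ids, rownames(G$geno))
  ri <- match(rec_ids, rownames(G$geno))
  .assert(!anyNA(oi) && !anyNA(ri), "metadata hybrid absent from genotypes")
  freq <- function(rows, col, fav_is_alt) {
    g <- G$geno[rows, col]
    g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_real_)
    p_alt <- mean(g) / 2
    if (fav_is_alt) p_alt else 1 - p_alt
  }
  res <- lapply(seq_len(nrow(effects)), function(i) {
    col <- match(effects$marker[i], G$map$id)
    if (is.na(col)) {
      return(data.frame(qtl = effects$qtl[i], marker = effects$marker[i],
                        class = effects$class[i], freq_old = NA_real_,
                        freq_recent = NA_real_, delta = NA_real_,
                        missing_marker = TRUE, stringsAsFactors = FALSE))
    }
    fav <- effects$favorable_allele[i]
    .assert(fav %in% c(G$map$ref[col], G$map$alt[col]),
            "favorable allele '%s' matches neither allele of %s",
            fav, effects$marker[i])
    fav_is_alt <- fav == G$map$alt[col]
    fo <- freq(oi, col, fav_is_alt)
    fr <- freq(ri, col, fav_is_alt)
    data.frame(qtl = effects$qtl[i], marker = effects$marker[i],
               class = effects$class[i], freq_old = fo, freq_recent = fr,
               delta = fr - fo, missing_marker = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
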