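# small in-code fixtures shared across test files

toy_map <- function(markers, pos, lg = "1", map_id = "m1") {
  genetic_map(data.frame(lg = lg, marker = markers, pos_cm = pos),
              map_id = map_id)
}

# a random one-LG map with n markers on [0, len], first marker at 0
random_map <- function(n, len = 100, map_id = "m", lg = "1") {
  pos <- sort(c(0, runif(n - 1L, 0, len)))
  toy_map(sprintf("mk%02d", seq_len(n)), pos, lg = lg, map_id = map_id)
}

# consensus_map wrapper around a plain marker table (for projection tests)
as_consensus <- function(markers) {
  markers$n_maps <- markers$n_maps %||% 2L
  structure(list(markers = markers, provenance = NULL),
            class = "consensus_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

qtl_row <- function(qtl_id = "q1", trait = "ver", lg = "1", peak = 10,
                    ci = c(8, 12), r2 = 0.1, study = "s1", n = 150L,
                    category = "phenology") {
  data.frame(qtl_id = qtl_id, trait = trait, trait_category = category,
             study_ref = study, population_size = n, lg = lg,
             peak_cm = peak, ci_start_cm = ci[1L], ci_end_cm = ci[2L],
             r2 = r2, ci_missing = FALSE, status = "projected",
             reason = NA_character_)
}
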