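# Shared fixtures, computed lazily and cached for the whole test session.
# The "study-scale" fixture mirrors the conditions exercised throughout the
# suite: 16 HIM-bearing segments, ~200 integrations (13 per segment),
# 30x depth, microhomologies 0-5 bp.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

study_config <- function(error_rate = 0, seed = 107L) {
  sim_config(host_length = 2e5, wasp_length = 1e5, n_segments = 16,
             n_integrations_per_segment = 13, depth_host = 30,
             depth_wasp = 30, depth_junction = 30,
             error_rate = error_rate, seed = seed)
}

study_report <- function() {
  fixture("study_report", function() {
    run_pipeline(pipeline_config(sim = study_config(), seed = 107L,
                                 ie_scope = "him"))
  })
}

study_report_err <- function() {
  fixture("study_report_err", function() {
    run_pipeline(pipeline_config(sim = study_config(error_rate = 0.001,
                                                    seed = 211L),
                                 seed = 211L, ie_scope = "him"))
  })
}

abundance_report <- function() {
  fixture("abundance_report", function() {
    cfg <- sim_config(host_length = 1.5e5, wasp_length = 5e4, n_segments = 5,
                      n_integrations_per_segment = c(2, 4, 8, 16, 32),
                      depth_host = 8, depth_wasp = 2, depth_junction = 25,
                      depth_circles = 5,
                      segment_copy_number = c(1, 2, 4, 8, 16), seed = 31)
    run_pipeline(pipeline_config(sim = cfg, seed = 31, ie_scope = "him"))
  })
}

abundance_depth_cor <- function() {
  rep <- abundance_report()
  sim <- rep$sim
  depths <- vapply(seq_len(nrow(sim$segments)), function(i) {
    nm <- paste0("circle_", sim$segments$segment_id[i])
    track <- depth_track_from_reads(sim$reads, nm, nchar(sim$circles[[nm]]))
    segment_depth(track, tibble::tibble(contig = nm, start = 1,
                                        end = nchar(sim$circles[[nm]])))
  }, numeric(1))
  names(depths) <- sim$segments$segment_id
  ies <- table(factor(rep$events$segment_id,
                      levels = sim$segments$segment_id))
  depth_ie_correlation(depths, setNames(as.numeric(ies), names(ies)))
}

small_sim <- function() {
  fixture("small_sim", function() {
    simulate_dataset(sim_config(host_length = 6e4, wasp_length = 4e4,
                                n_segments = 4,
                                n_integrations_per_segment = 5,
                                depth_host = 5, depth_wasp = 5,
                                depth_junction = 20, seed = 42L))
  })
}

junction_key <- function(x, host_col, wasp_col, flank_col) {
  paste(x$segment_id, x[[host_col]], x[[wasp_col]], x$orientation,
        x[[flank_col]])
}

truth_keys <- function(sim) {
  junction_key(sim$junctions, "junction_host", "junction_wasp", "flank")
}

event_keys <- function(events) {
  junction_key(events, "host_position", "junction_on_wasp", "host_flank")
}
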