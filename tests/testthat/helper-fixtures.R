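# Shared fixtures built in code: tiny plate tables and standard designs.

log_spaced <- function(from = 0.1, to = 100, n = 8) {
  10^seq(log10(from), log10(to), length.out = n)
}

# Minimal one-run plate table: n_comp compound wells + n_ctrl DMSO wells on
# each of the three sample-type plates, with explicit lifetimes/intensities.
tiny_run <- function(tau_da_comp, tau_da_ctrl,
                     tau_don_comp = rep(4, length(tau_da_comp)),
                     tau_don_ctrl = rep(4, length(tau_da_ctrl)),
                     int_comp = rep(1000, length(tau_da_comp)),
                     int_ctrl = rep(1000, length(tau_da_ctrl))) {
  n_comp <- length(tau_da_comp); n_ctrl <- length(tau_da_ctrl)
  ids <- sprintf("CMP-%03d", seq_len(n_comp))
  wells_c <- sprintf("A%02d", seq_len(n_comp))
  wells_d <- sprintf("B%02d", seq_len(n_ctrl))
  one <- function(st, tc, td, ic, id2) rbind(
    data.frame(plate_id = paste0("p_", st), run_id = 1, read_time_min = 120,
               well = wells_c, row = 1, col = seq_len(n_comp),
               sample_type = st, compound_id = ids, tau_ns = tc,
               integrated_intensity = ic),
    data.frame(plate_id = paste0("p_", st), run_id = 1, read_time_min = 120,
               well = wells_d, row = 2, col = seq_len(n_ctrl),
               sample_type = st, compound_id = "DMSO", tau_ns = td,
               integrated_intensity = id2)
  )
  rbind(one("donor_acceptor", tau_da_comp, tau_da_ctrl,
            rep(1000, n_comp), rep(1000, n_ctrl)),
        one("donor_only", tau_don_comp, tau_don_ctrl,
            rep(1000, n_comp), rep(1000, n_ctrl)),
        one("unlabeled", rep(NA_real_, n_comp), rep(NA_real_, n_ctrl),
            int_comp, int_ctrl))
}

# Build a normalized_plate object directly from chosen E/E0 values
# (control mean/SD given explicitly), for threshold boundary tests.
fake_normalized <- function(comp_ratio, ctrl_mean = 1, ctrl_sd = 0.016) {
  df <- data.frame(
    well = sprintf("A%02d", seq_along(comp_ratio)),
    sample_type = "donor_acceptor",
    compound_id = sprintf("CMP-%03d", seq_along(comp_ratio)),
    tau_ns = NA_real_, E = 0.2 * comp_ratio, E_ratio = comp_ratio)
  structure(df, tau_D = 4, E0 = 0.2, control_mean_ratio = ctrl_mean,
            control_sd_ratio = ctrl_sd, n_control = 256,
            class = c("normalized_plate", "data.frame"))
}
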