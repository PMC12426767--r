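# Benchmark convergence studies shared by the acceptance tests; each is
# computed once per test run at the canonical suite resolutions.

study_2d_p1p1 <- function() {
  fixture("acc_2d_p1p1", function() {
    run_convergence_study("stokes2d", "P1P1_stabilized",
                          levels = benchmark_suite_levels()$stokes2d_p1p1,
                          wss_methods = c("bflux_p1", "proj_p1", "proj_dg1",
                                          "proj_dg0"))
  })
}

study_2d_p2p1 <- function() {
  fixture("acc_2d_p2p1", function() {
    run_convergence_study("stokes2d", "P2P1",
                          levels = benchmark_suite_levels()$stokes2d_p2p1,
                          wss_methods = c("bflux_p1", "bflux_p2", "proj_p1",
                                          "proj_dg1", "proj_dg0"))
  })
}

study_3d_p1p1 <- function() {
  fixture("acc_3d_p1p1", function() {
    run_convergence_study("poiseuille", "P1P1_stabilized",
                          levels = benchmark_suite_levels()$poiseuille_p1p1,
                          wss_methods = c("bflux_p1", "proj_p1", "proj_dg1",
                                          "proj_dg0"))
  })
}

study_3d_p2p1 <- function() {
  fixture("acc_3d_p2p1", function() {
    run_convergence_study("poiseuille", "P2P1",
                          levels = benchmark_suite_levels()$poiseuille_p2p1,
                          wss_methods = c("bflux_p1", "bflux_p2", "proj_p1",
                                          "proj_dg1", "proj_dg0"))
  })
}

study_3d_p2p1_bl <- function() {
  fixture("acc_3d_p2p1_bl", function() {
    run_convergence_study("poiseuille", "P2P1",
                          levels = benchmark_suite_levels()$poiseuille_p2p1_bl,
                          wss_methods = c("bflux_p1", "bflux_p2", "proj_p1"),
                          mesh_family = "boundary_layer")
  })
}
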