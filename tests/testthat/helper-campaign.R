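# The end-to-end mini campaign is expensive; build it once and share it
# across the acceptance checks that need it.
campaign_env <- new.env()

get_campaign <- function(seed = 1L) {
  if (is.null(campaign_env$campaign)) {
    cfg <- experiment_config("mini")
    fixture <- make_fixture(cfg, seed = seed)
    campaign_env$fixture <- fixture
    campaign_env$campaign <- run_experiment(cfg, seed = seed,
                                            fixture = fixture,
                                            keep_details = FALSE)
  }
  campaign_env$campaign
}

get_perturbations <- function(seed = 1L) {
  if (is.null(campaign_env$perturb)) {
    camp <- get_campaign(seed)
    fx <- camp$fixture
    # one study per trained target network, pooled
    tabs <- lapply(names(fx$nets), function(lab) {
      st <- perturbation_correlation_study(
        fx$nets[[lab]], fx$arm, fx$targets[lab],
        n_perturbations = fx$config$n_perturbations / 2,
        seed = derive_seed(seed, paste0("perturb_", lab)))
      st$table
    })
    tab <- do.call(rbind, tabs)
    sm <- c("spike_dist", "spike_sync", "peth_r")
    bm <- c("final_distance", "mean_pointwise")
    cors <- matrix(NA_real_, 3, 2, dimnames = list(sm, bm))
    pv <- cors
    for (i in sm) for (j in bm) {
      ct <- stats::cor.test(tab[[i]], tab[[j]])
      cors[i, j] <- unname(ct$estimate)
      pv[i, j] <- ct$p.value
    }
    campaign_env$perturb <- list(table = tab, correlations = cors,
                                 p_values = pv,
                                 mean_abs_R = mean(abs(cors)))
  }
  campaign_env$perturb
}
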