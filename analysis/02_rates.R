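#!/usr/bin/env Rscript
# Metabolite balancing on the generated batch culture: specific growth
# rate, constant cell-specific extracellular rates (glutamine with
# first-order abiotic degradation) and the carbon-source accounting of
# central metabolism.

library(instcho)

culture <- read.csv("results/synthetic/culture.csv")
dir.create("results/rates", showWarnings = FALSE, recursive = TRUE)

growth <- fit_growth(culture)
print(growth)

rates <- fit_all_rates(culture, growth, kd = c(GLN_ex = 0.0033))
write.csv(rates, "results/rates/extracellular_rates.csv", row.names = FALSE)
print(rates, digits = 4)

# degradation-aware vs naive glutamine uptake
gln_kd <- fit_rate(culture, growth, "GLN_ex", kd = 0.0033)
gln_0 <- fit_rate(culture, growth, "GLN_ex", kd = 0)
cat(sprintf("glutamine uptake %.1f with degradation vs %.1f without (%.1f%% smaller)\n",
            -gln_kd$v, -gln_0$v, 100 * (abs(gln_0$v) - abs(gln_kd$v)) / abs(gln_0$v)))

# carbon sources feeding central metabolism
net <- load_network(cho_network_path("compartmented"))
v <- function(m) -rates$v[rates$metabolite == m]
up <- c(Glucose = v("GLC_ex"), Glutamine = v("GLN_ex"),
        AA1 = net$measured$aa1_cat$value, AA2 = net$measured$aa2_cat$value,
        AA3 = net$measured$aa3_cat$value,
        ASP_ASN = v("ASP_ex") + v("ASN_ex") - net$measured$bm_asn$value,
        Serine = v("SER_ex"))
carb <- c(Glucose = 6, Glutamine = 5, AA1 = 2, AA2 = 4, AA3 = 5,
          ASP_ASN = 4, Serine = 3)
tab <- carbon_accounting(up, carb)
write.csv(tab, "results/rates/carbon_sources.csv", row.names = FALSE)
print(tab, digits = 4)
cat(sprintf("glucose provides %.1f%% of the carbon entering central metabolism\n",
            tab$percent[tab$source == "Glucose"]))
lac_glc <- -rates$v[rates$metabolite == "LAC_ex"] / rates$v[rates$metabolite == "GLC_ex"]
cat(sprintf("lactate/glucose molar ratio %.2f -> %.0f%% of glucose overflows to lactate\n",
            lac_glc, 100 * lac_glc / 2))
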