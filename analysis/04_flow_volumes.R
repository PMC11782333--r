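#!/usr/bin/env Rscript
# Turn the simulated Doppler-ultrasound table into per-vessel blood flow
# volumes (TAV x CSA x 60) and the venous BFV (PA + DA, both afferent in
# these retrograde-flow fistulae).

suppressMessages(library(avfsound))

us <- read.csv("results/inputs/us.csv")
bfv <- flow_metrics_table(us)
write.csv(bfv, "results/bfv.csv", row.names = FALSE)

ba <- bfv[bfv$vessel == "BA", ]
ven <- bfv[bfv$vessel == "VEN", ]
cat(sprintf("BFV computed for %d vessel measurements -> results/bfv.csv\n",
            sum(bfv$vessel != "VEN")))
cat(sprintf("Brachial BFV %.0f-%.0f mL/min; venous (PA+DA) %.0f-%.0f mL/min\n",
            min(ba$bfv_ml_min), max(ba$bfv_ml_min),
            min(ven$bfv_ml_min), max(ven$bfv_ml_min)))
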