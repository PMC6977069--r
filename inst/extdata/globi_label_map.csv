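raw_label,interaction_type
eatenBy,predation
eats,predation
preysOn,predation
preyedUponBy,predation
parasiteOf,parasitism
hasParasite,parasitism
parasitizedBy,parasitism
pathogenOf,parasitism
symbiontOf,symbiosis
hasSymbiont,symbiosis
mutualistOf,mutualism
commensalistOf,symbiosis
epibiontOf,epibiosis
hasEpibiont,epibiosis
livesOn,epibiosis
epiphyteOf,epibiosis
allelopathOf,allelopathy
competesWith,competition
predation,predation
parasitism,parasitism
symbiosis,symbiosis
epibiosis,epibiosis
allelopathy,allelopathy
competition,competition
mutualism,mutualism
epipsammic,nonliving
epipelic,nonliving
livesOnSand,nonliving
livesOnMud,nonliving
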