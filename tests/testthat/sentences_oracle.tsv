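text	sentences
The model fits. The test was significant (p < .05).	The model fits.|The test was significant (p < .05).
Estimates (M = 3.5, SD = 1.2) were stable.	Estimates (M = 3.5, SD = 1.2) were stable.
Smith et al. (2020) agree. We concur.	Smith et al. (2020) agree.|We concur.
J. R. Smith and M. K. Lee replied. Their reply was short.	J. R. Smith and M. K. Lee replied.|Their reply was short.
See Fig. 3 for details. The effect is shown in Fig. 4.	See Fig. 3 for details.|The effect is shown in Fig. 4.
Values differ (cf. Table 2). No correction was applied.	Values differ (cf. Table 2).|No correction was applied.
The mean was 3.14 in group A. Group B scored 2.71.	The mean was 3.14 in group A.|Group B scored 2.71.
Participants were tested twice, i.e. before and after treatment.	Participants were tested twice, i.e. before and after treatment.
Stimuli included words, pictures, etc. and were randomised.	Stimuli included words, pictures, etc. and were randomised.
Alpha was set to .05. Power was computed afterwards.	Alpha was set to .05.|Power was computed afterwards.
Dr. Meyer approved the protocol. Prof. Chan disagreed.	Dr. Meyer approved the protocol.|Prof. Chan disagreed.
The sample size was 120. All subjects consented!	The sample size was 120.|All subjects consented!
Was the effect real? It was not.	Was the effect real?|It was not.
Results replicated (see Appendix B). This was expected.	Results replicated (see Appendix B).|This was expected.
The p-value was p = .001. Effect sizes were large.	The p-value was p = .001.|Effect sizes were large.
Groups A and B differed. Group C did not.	Groups A and B differed.|Group C did not.
Means (3.5 vs. 4.2) differed. Variances were equal.	Means (3.5 vs. 4.2) differed.|Variances were equal.
Items were scored 1-5. Higher scores mean agreement.	Items were scored 1-5.|Higher scores mean agreement.
The assay ran overnight. Samples were stored at 4 degrees.	The assay ran overnight.|Samples were stored at 4 degrees.
E. coli cultures grew slowly. Yeast grew faster.	E. coli cultures grew slowly.|Yeast grew faster.
Scores improved by 12.5 percent. The gain persisted.	Scores improved by 12.5 percent.|The gain persisted.
No. 7 performed best. No. 9 failed.	No. 7 performed best.|No. 9 failed.
Testing lasted 2 h. Breaks were allowed.	Testing lasted 2 h.|Breaks were allowed.
Responses (approx. 80%) were valid. The rest were excluded.	Responses (approx. 80%) were valid.|The rest were excluded.
All tests were two-sided! Alpha was .05.	All tests were two-sided!|Alpha was .05.
First we cleaned the data. Then we fit the model. Finally we checked residuals.	First we cleaned the data.|Then we fit the model.|Finally we checked residuals.
The survey took 20 min. Items used a 7-point scale. Refusals were rare.	The survey took 20 min.|Items used a 7-point scale.|Refusals were rare.
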