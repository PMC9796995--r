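@Begin
@Languages:	eng
@Participants:	PAR Participant, INV Investigator
@ID:	eng|example|PAR|||||Participant|||
*INV:	tell me as many words as you can that start with f .
*PAR:	find fire fry fly .
*PAR:	food [x 2] fox .
%com:	pause
*INV:	anything else ?
*PAR:	dog fertile
	fen .
@End
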