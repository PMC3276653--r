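animal	subgroup	proximal	distal	both
L1	lean2	q	q	q-q
L2	lean2	Q	q	Q-q
L3	lean1	q	Q	q-Q
L4	lean1	Q	q	Q-q
L5	lean1	Q	q	Q-q
L6	lean1	q	x	X
L7	lean2	Q	x	X
L8	lean1	q	Q	q-Q
L9	mixed	q	q	q-q
L10	lean1	x	q	X
L11	lean1	x	q	X
L12	lean1	q	q	q-q
L13	fat2	x	Q	X
L14	lean1	Q	q	Q-q
L15	lean1	x	Q	X
L16	lean2	q	x	X
L17	lean2	Q	q	Q-q
L18	mixed	Q	Q	Q-Q
L19	lean2	Q	q	Q-q
L20	fat2	q	q	q-q
I1	mixed	x	Q	X
I2	fat2	x	Q	X
I3	mixed	q	q	q-q
I4	mixed	Q	Q	Q-Q
I5	mixed	Q	q	Q-q
F1	fat1	Q	Q	Q-Q
F2	mixed	Q	Q	Q-Q
F3	fat2	Q	Q	Q-Q
F4	fat2	Q	Q	Q-Q
F5	fat1	Q	x	X
F6	fat1	q	q	q-q
F7	fat1	Q	Q	Q-Q
F8	mixed	x	Q	X
F9	fat1	Q	x	X
F10	fat1	q	q	q-q
F11	fat2	x	q	X
F12	fat2	Q	Q	Q-Q
F13	mixed	q	q	q-q
F14	fat1	x	Q	X
F15	fat2	x	Q	X
F16	lean2	q	q	q-q
F17	fat1	x	Q	X
F18	fat2	Q	Q	Q-Q
F19	fat2	Q	Q	Q-Q
F20	mixed	q	Q	q-Q
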