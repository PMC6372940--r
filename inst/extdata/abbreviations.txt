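dr.
mr.
mrs.
ms.
prof.
st.
jr.
sr.
e.g.
i.e.
etc.
vs.
fig.
al.
no.
dept.
approx.
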