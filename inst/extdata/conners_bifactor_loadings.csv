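item,label,subscale,general,inattention,hyperactivity
1,Struggles paying attention,Inattention,0.53,0.50,0.04
2,Makes mistakes,Inattention,0.40,0.38,0.01
3,Struggles focusing on tasks,Inattention,0.59,0.57,0.02
4,Struggles focusing on conversations,Inattention,0.56,0.50,0.06
5,Struggles following instructions,Inattention,0.56,0.52,0.04
6,Struggles finishing tasks,Inattention,0.52,0.55,-0.03
7,Struggles with organisation,Inattention,0.46,0.53,-0.07
8,Dislikes complex tasks,Inattention,0.34,0.38,-0.04
9,Loses things,Inattention,0.47,0.38,0.09
10,Gets distracted,Inattention,0.59,0.46,0.13
11,Forgets things,Inattention,0.50,0.47,0.03
12,Struggles sitting still,Hyperactivity,0.53,0.14,0.39
13,Leaves seat inappropriately,Hyperactivity,0.57,0.19,0.38
14,Feels restless,Hyperactivity,0.56,0.19,0.36
15,Struggles remaining quiet,Hyperactivity,0.58,0.10,0.48
16,Prefers being on the go,Hyperactivity,0.29,-0.08,0.37
17,Talks too much,Hyperactivity,0.41,-0.13,0.54
18,Blurts out answers to questions,Hyperactivity,0.47,-0.09,0.56
19,Struggles waiting turns,Hyperactivity,0.53,-0.03,0.55
20,Interrupts others,Hyperactivity,0.45,-0.02,0.48
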